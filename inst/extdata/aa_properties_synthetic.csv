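aa,prop001,prop002,prop003,prop004,prop005,prop006,prop007,prop008,prop009,prop010,prop011,prop012,prop013,prop014,prop015,prop016,prop017,prop018,prop019,prop020,prop021,prop022,prop023,prop024,prop025,prop026,prop027,prop028,prop029,prop030
A,1.8,88.6,0,-5.793,-3.163,0.994,-3.657,4.666,-4.556,1.578,-3.128,-1.855,-0.333,0.922,0.055,-2.645,4.67,-4.597,-0.725,-1.622,-2.355,3.693,3.498,0.586,3.092,-1.203,0.506,-6.394,-0.696,6.143
C,2.5,108.5,0,-3.052,-3.337,-1.161,-3.08,3.393,-3.921,0.959,-2.678,-0.673,0.369,1.41,4.43,-1.011,2.878,-3.778,-0.938,-0.146,-1.42,0.93,1.726,-0.598,0.857,1.052,-0.467,-6.196,0.554,6.227
D,-3.5,111.1,-1,-2.655,-2.396,-0.724,-3.213,3.341,-3.936,1.011,-1.83,2.047,-0.037,0.942,2.018,-1.381,2.449,-1.702,1.202,-1.104,-5.42,0.669,1.146,-1.669,1.196,0.82,-0.387,-6.358,1.591,5.453
E,-3.5,138.4,-1,-0.24,-3.159,-1.181,-1.163,2.715,-2.719,3.146,-1.447,1.658,0.946,-0.313,4.84,-0.031,0.386,-1.98,0.08,-0.866,-3.087,-1.218,-0.46,-1.257,-0.37,-0.406,-1.196,-5.29,4.626,3.155
F,2.8,189.9,0,0.229,-1.948,-3.793,-0.391,-0.131,-0.674,3.93,-0.121,3.076,3.183,-2.385,8.094,2.395,-0.547,-7.003,-0.794,2.084,-1.151,-2.604,-4.203,-2.538,-3.174,3.193,-3.422,-2.997,5.525,0.021
G,-0.4,60.1,0,-2.265,-6.313,-0.206,-6.283,5.788,-5.785,0.634,-3.602,-4.316,-1.409,2.11,-0.929,-3.251,5.913,0.057,0.977,-2.776,-3.962,2.441,5.034,0.566,3.868,-2.545,1.806,-7.338,0.18,4.863
H,-3.2,153.2,0.1,-1.765,-5.105,-4.707,-1.503,1.067,-1.18,3.324,-0.586,1.115,1.733,-0.469,5.146,0.612,-0.767,-4.748,-0.52,0.212,-2.838,-0.825,-0.938,-1.066,-1.504,2.46,-1.315,-3.234,1.731,2.443
I,4.5,166.7,0,0.047,-2.981,-4.309,-0.746,1.024,-1.167,1.318,-1.423,1.711,2.473,-1.968,3.188,0.72,-0.463,-6.555,-1.419,2.435,-3.139,-2.405,-1.527,-1.168,-0.026,2.016,-3.164,-2.217,5.8,3.423
K,-3.9,168.6,1,-2.971,-4.19,-2.586,-1.911,1.28,-2.061,2.893,-1.893,2.41,3.256,-1.169,2.813,0.225,0.265,-5.558,0.576,0.647,-1.843,-0.286,-2.844,-2.089,-1.168,2.057,-2.27,-3.031,3.824,1.765
L,3.8,166.7,0,-2.532,-2.169,-1.47,-0.382,0.706,-2.257,2.86,-2.313,1.304,1.621,-0.64,5.069,1.227,-0.32,-6.317,-0.259,1.289,-3.07,-1.859,-1.817,-1.736,-1.488,4.137,-3.024,-3.429,4.603,0.346
M,1.9,162.9,0,0.78,-0.648,-2.56,0.749,0.536,-2.149,4.92,-0.248,0.676,1.74,-0.784,5.669,1.103,-0.99,-3.678,0.07,0.789,-0.22,-0.249,-1.8,-0.97,0.151,1.26,-2.231,-4.031,4.198,2.078
N,-3.5,114.1,0,-2.173,-4.87,-1.061,-4.492,2.908,-3.689,2.801,-1.865,-1.303,0.586,1.257,1.108,-1.085,2.1,-1.369,-0.022,-1.793,-2.053,1.212,1.083,-0.363,1.193,-0.784,-0.64,-5.946,1.077,3.967
P,-1.6,112.7,0,-1.643,-2.968,-1.965,-3.117,4.039,-4.509,1.255,-3.501,-0.863,-1.061,0.838,3.367,-1.503,2.023,-3.502,-0.124,-1.067,-3.069,1.1,1.352,0.12,2.028,0.669,0.108,-5.928,0.121,4.389
Q,-3.5,143.8,0,-2.227,0.229,-2.695,-2.737,2.493,-0.941,3.394,-1.389,0.638,1.894,-0.285,4.06,0.304,-0.409,-1.522,-1.417,-0.059,-1.744,-0.552,-0.773,-1.389,-0.35,2.769,-1.159,-4.544,3.058,4.075
R,-4.5,173.4,1,-1.181,-2.272,-1.464,-1.184,0.837,-1.671,3.335,-1.049,1.67,2.896,-1.412,3.738,1.492,-1.139,-2.531,1.773,1.159,-3.833,-2.205,-3.636,-1.55,-0.134,2.534,-2.44,-2.437,2.369,2.463
S,-0.8,89,0,0.149,-5.395,0.063,-7.729,5.07,-5.231,-0.148,-3.398,-2.208,-0.313,0.545,-0.35,-2.454,3.056,-0.925,-0.909,-1.448,-4.239,2.305,3.118,1.333,3.83,-1.703,0.636,-6.417,-0.499,2.498
T,-0.7,116.1,0,-0.427,-3.25,2.129,-4.199,4.024,-4.16,3.691,-3.242,-1.988,0.089,0.702,1.884,-1.391,1.878,-3.239,-3.026,-0.826,-1.276,1.051,1.444,-0.734,1.784,-0.229,-0.191,-5.066,-0.473,2.506
V,4.2,140,0,-1.73,-5.103,-2.703,-0.744,1.502,-2.532,1.321,-2.066,2.263,1.622,-0.557,3,-0.559,1.011,-4.067,-2.163,0.621,-2.655,-0.072,-0.189,-0.015,-0.207,0.548,-1.41,-5.362,0.972,2.753
W,-0.9,227.8,0,0.602,-2.932,-5.471,1.964,-1.225,1.642,6.292,-0.58,3.804,4.642,-2.456,8.18,3.509,-4.314,-7.734,0.449,3.121,-0.49,-3.431,-6.827,-3.189,-5.949,5.82,-5.02,-0.594,7.785,0.333
Y,-1.3,193.6,0,1.958,-2.816,-3.942,-1.684,-0.336,-0.599,4.126,-1.323,3.02,3.625,-2.937,4.892,2.024,-2.623,-5.305,-0.122,2.383,-0.406,-3.932,-4.729,-2.378,-2.58,4.772,-2.961,-1.825,7.507,1.396
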