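tf,split,set,n,r2,ccc,iic,cii,q2,rmse,f,n_attr
TF0,1,C,210,0.5556,0.7446,0.7426,0.7801,0.5425,0.759,260,
TF0,1,V,216,0.733,,,,,0.55,,77
TF0,2,C,210,0.3224,0.5659,0.4548,0.7263,0.2926,0.893,99,
TF0,2,V,216,0.3787,,,,,0.91,,74
TF0,3,C,210,0.4081,0.6297,0.5581,0.7572,0.3886,0.893,143,
TF0,3,V,216,0.7462,,,,,0.54,,79
TF0,4,C,210,0.4401,0.6372,0.5241,0.7715,0.4233,0.91,163,
TF0,4,V,216,0.7545,,,,,0.70,,77
TF0,5,C,210,0.459,0.6713,0.6585,0.7367,0.4433,0.918,176,
TF0,5,V,216,0.5537,,,,,0.85,,74
TF1,1,C,210,0.719,0.8308,0.8479,0.832,0.7129,0.503,532,
TF1,1,V,216,0.8221,,,,,0.48,,77
TF1,1,Vad,195,0.8391,,,,,0.48,,
TF1,2,C,210,0.734,0.8413,0.8567,0.8505,0.7289,0.404,574,
TF1,2,V,216,0.7703,,,,,0.45,,78
TF1,3,C,210,0.7208,0.8291,0.849,0.8463,0.7162,0.405,537,
TF1,3,V,216,0.7817,,,,,0.45,,76
TF1,4,C,210,0.6849,0.821,0.827,0.8349,0.6787,0.438,452,
TF1,4,V,216,0.7351,,,,,0.47,,74
TF1,5,C,210,0.7357,0.8479,0.8576,0.855,0.7305,0.44,579,
TF1,5,V,216,0.7212,,,,,0.48,,70
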