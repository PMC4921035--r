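control_id,subpool,base_abundance,antisense,non_srm,reassigned_subpool
ERCC-00073,omitted,0,FALSE,FALSE,
ERCC-00162,A,1,FALSE,FALSE,
ERCC-00154,A,2,FALSE,FALSE,
ERCC-00144,A,4,FALSE,FALSE,
ERCC-00136,A,8,FALSE,FALSE,
ERCC-00126,A,16,FALSE,FALSE,
ERCC-00108,A,32,TRUE,FALSE,
ERCC-00096,A,64,FALSE,FALSE,
ERCC-00053,A,128,FALSE,FALSE,
ERCC-00077,A,256,FALSE,FALSE,
ERCC-00071,A,512,FALSE,FALSE,
ERCC-00060,A,1024,FALSE,FALSE,
ERCC-00084,A,2048,FALSE,FALSE,
ERCC-00043,A,4096,FALSE,FALSE,
ERCC-00035,A,8192,FALSE,FALSE,
ERCC-00025,A,16384,FALSE,FALSE,
ERCC-00079,A,32768,FALSE,FALSE,
ERCC-00170,A,65536,FALSE,FALSE,
ERCC-00003,A,262144,FALSE,FALSE,
ERCC-00012,A,1048576,FALSE,FALSE,
ERCC-00114,A,131072,FALSE,TRUE,
ERCC-00163,B,1,FALSE,FALSE,
ERCC-00156,B,2,FALSE,FALSE,
ERCC-00145,B,4,FALSE,FALSE,
ERCC-00137,B,8,FALSE,FALSE,
ERCC-00128,B,16,FALSE,FALSE,
ERCC-00116,B,32,TRUE,FALSE,
ERCC-00109,B,64,FALSE,FALSE,
ERCC-00097,B,128,FALSE,FALSE,
ERCC-00085,B,256,FALSE,FALSE,
ERCC-00078,B,512,FALSE,FALSE,
ERCC-00171,B,1024,FALSE,FALSE,
ERCC-00054,B,2048,FALSE,FALSE,
ERCC-00044,B,4096,FALSE,FALSE,
ERCC-00039,B,8192,FALSE,FALSE,
ERCC-00028,B,16384,FALSE,FALSE,
ERCC-00019,B,32768,FALSE,FALSE,
ERCC-00061,B,65536,FALSE,FALSE,
ERCC-00013,B,262144,FALSE,FALSE,
ERCC-00002,B,1048576,FALSE,FALSE,
ERCC-00164,C,1,FALSE,FALSE,
ERCC-00157,C,2,FALSE,FALSE,
ERCC-00147,C,4,FALSE,FALSE,
ERCC-00138,C,8,FALSE,FALSE,
ERCC-00130,C,16,FALSE,FALSE,
ERCC-00117,C,32,FALSE,FALSE,
ERCC-00111,C,64,FALSE,FALSE,
ERCC-00098,C,128,FALSE,FALSE,
ERCC-00086,C,256,FALSE,FALSE,
ERCC-00004,C,512,FALSE,FALSE,
ERCC-00074,C,1024,FALSE,FALSE,
ERCC-00057,C,2048,TRUE,FALSE,
ERCC-00062,C,4096,FALSE,FALSE,
ERCC-00046,C,8192,FALSE,FALSE,
ERCC-00040,C,16384,FALSE,FALSE,
ERCC-00051,C,32768,FALSE,FALSE,
ERCC-00022,C,65536,FALSE,FALSE,
ERCC-00014,C,262144,TRUE,FALSE,
ERCC-00018,C,1048576,FALSE,FALSE,
ERCC-00165,D,1,FALSE,FALSE,
ERCC-00158,D,2,FALSE,FALSE,
ERCC-00148,D,4,FALSE,FALSE,
ERCC-00142,D,8,FALSE,FALSE,
ERCC-00131,D,16,FALSE,FALSE,
ERCC-00120,D,32,FALSE,FALSE,
ERCC-00099,D,64,TRUE,FALSE,
ERCC-00112,D,128,FALSE,FALSE,
ERCC-00092,D,256,FALSE,FALSE,
ERCC-00081,D,512,FALSE,FALSE,
ERCC-00075,D,1024,FALSE,FALSE,
ERCC-00058,D,2048,FALSE,FALSE,
ERCC-00067,D,4096,FALSE,FALSE,
ERCC-00048,D,8192,FALSE,FALSE,
ERCC-00041,D,16384,FALSE,FALSE,
ERCC-00033,D,32768,FALSE,FALSE,
ERCC-00007,D,65536,FALSE,FALSE,
ERCC-00023,D,262144,FALSE,FALSE,
ERCC-00016,D,1048576,FALSE,FALSE,
ERCC-00123,E,1,FALSE,FALSE,
ERCC-00160,E,2,FALSE,FALSE,
ERCC-00150,E,4,FALSE,FALSE,
ERCC-00143,E,8,FALSE,FALSE,
ERCC-00134,E,16,FALSE,FALSE,
ERCC-00113,E,32,FALSE,FALSE,C
ERCC-00168,E,64,FALSE,FALSE,
ERCC-00104,E,128,FALSE,FALSE,
ERCC-00095,E,256,FALSE,FALSE,
ERCC-00083,E,512,FALSE,FALSE,
ERCC-00076,E,1024,FALSE,FALSE,
ERCC-00069,E,2048,FALSE,FALSE,
ERCC-00059,E,4096,TRUE,FALSE,
ERCC-00031,E,8192,FALSE,FALSE,
ERCC-00042,E,16384,FALSE,FALSE,
ERCC-00034,E,32768,FALSE,FALSE,
ERCC-00009,E,65536,TRUE,FALSE,
ERCC-00017,E,262144,FALSE,FALSE,
ERCC-00024,E,1048576,FALSE,FALSE,
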