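0.004 0.006 0.928 0.009 0.038 0.015
0.237 0.228 0.293 0.242 0 0
0.362 0.220 0.279 0.139 0 0
0.131 0.053 0.764 0.052 0 0
0.232 0.277 0.277 0.214 0 0
0.493 0.507 0 0 0 0
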