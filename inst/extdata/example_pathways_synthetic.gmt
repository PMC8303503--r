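PW_GROWTH	synthetic toy growth signalling pathway	GS0001:+1	GS0002:+1	GS0003:+1	GS0004:+1	GS0005:+1	GS0006:-1	GS0007:-1	GS0008:+1	GS0009:+1	GS0010:+1	GS0011:+1	GS0012:-1
PW_ECM	synthetic toy extracellular matrix pathway	GS0013:+1	GS0014:+1	GS0015:+1	GS0016:+1	GS0017:+1	GS0018:+1	GS0019:-1	GS0020:+1	GS0021:+1	GS0022:+1
PW_SMALL	synthetic toy pathway below the size filter	GS0023:+1	GS0024:-1	GS0025:+1
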