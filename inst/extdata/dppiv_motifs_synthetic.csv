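sequence,activity,ic50_uM
IP,DPP-IV inhibitor,410
VP,DPP-IV inhibitor,880
FP,DPP-IV inhibitor,363
AP,DPP-IV inhibitor,7950
GP,DPP-IV inhibitor,9690
LP,DPP-IV inhibitor,2370
IPI,DPP-IV inhibitor,3.5
VPL,DPP-IV inhibitor,15.8
FPL,DPP-IV inhibitor,321.5
FPH,DPP-IV inhibitor,500
FDL,DPP-IV inhibitor,800
YPW,DPP-IV inhibitor,250
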