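id,log_s,censored,gsk_class,source
MZ1,-4.42,FALSE,intermediate,printed
MZP-54,-6.29,FALSE,low,printed
dBET57,-4.52,FALSE,intermediate,printed
ZXH-3-26,-5.53,FALSE,low,printed
BI-3663,-5.16,FALSE,low,printed
BI-0319,-5.58,FALSE,low,printed
BI-4206,-6.24,FALSE,low,printed
BSJ-03-123,,FALSE,low,printed_class_only
VZ185,,FALSE,,named_only
CM11,,FALSE,high,printed_class_only
CMP98,,FALSE,high,printed_class_only
BRD9-degrader,,FALSE,high,printed_class_only
ACBI1,,TRUE,low,printed_nd
cisACBI1,,TRUE,low,printed_nd
ARV-825,,TRUE,low,printed_nd
Mcl1-degrader-1,,TRUE,low,printed_nd
MD-224,,TRUE,low,printed_nd
SYN-STUB-01,,FALSE,,synthetic
SYN-STUB-02,,FALSE,,synthetic
SYN-STUB-03,,FALSE,,synthetic
SYN-STUB-04,,FALSE,,synthetic
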