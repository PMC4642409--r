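chemo brain
pet scan
bone scan
esophageal cancer
breast cancer
prostate cancer
pancreatic cancer
blood test
hot flash
triple negative
radiation therapy
lymph node
side effect
hair loss
tumor marker
stage 4
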