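survivorgirl
pinkwarrior
hopeful2010
braveheart22
chemochamp
stage4strong
fighterdan
nedforever
marathonmom
grammyjo
texasrose
seasidesue
warriorbill
lakehouselynn
mountainman55
quiltingkay
gardengal
bluebird77
nightowlnurse
sunshinestate
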