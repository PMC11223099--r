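name,pKa,cLogP,class_hint
synthetic CAD high-risk A,9.4,3.9,cationic amphiphile
synthetic CAD high-risk B,8.9,4.6,cationic amphiphile
synthetic borderline C,8.0,3.9,cationic amphiphile
synthetic borderline D,7.6,4.4,cationic amphiphile
synthetic neutral lipophile E,1.2,4.1,neutral
synthetic hydrophilic base F,9.1,-0.8,hydrophilic
synthetic low-risk G,5.0,2.0,weak base
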