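label	tail_carbons	topology
C12H22O4	12	cyclic
C14H27O4	14	linear
C15H29O4	15	linear
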