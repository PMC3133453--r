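name,preference,note
Neutrase,YWF,"neutral protease; C-terminal Tyr/Trp/Phe"
Alcalase,ILVMFYW,"alkaline protease; large uncharged side chains at C-terminus"
Proteinase K,FYVILWPM,"broad serine protease"
Chymotrypsin C,YLWPMEK,"chymotrypsin C"
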