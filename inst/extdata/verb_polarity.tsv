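lemma	class
associate	positive
link	positive
correlate	positive
relate	positive
implicate	positive
confer	positive
predispose	positive
increase	positive
elevate	positive
contribute	positive
predict	positive
connect	positive
couple	positive
involve	positive
protect	negative
decrease	negative
reduce	negative
diminish	negative
lower	negative
investigate	investigatory
examine	investigatory
study	investigatory
evaluate	investigatory
assess	investigatory
explore	investigatory
analyze	investigatory
analyse	investigatory
determine	investigatory
screen	investigatory
survey	investigatory
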