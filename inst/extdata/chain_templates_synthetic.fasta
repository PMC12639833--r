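>CL_SYNTH synthetic light-chain constant-domain template (not a natural sequence)
DHGKPQETTRVIVGEFLAGGFVSRYQIGESSKIPPRDLSIRGKENKERDYRGAKHFGVAL
TKVQADVGQYSGVSINAYLIQYDAFAPSAVLFADHTNAQKSFNRGEC
>CH1_SYNTH synthetic heavy-chain CH1+hinge template, ends at the IdeS cleavage motif (not a natural sequence)
ISESRPRALLTKIAILGKLGSPENIINLGYIDEVDPCQWNPMNDCVLIQISRFLETPAIS
MLCLADFDGPKARLVNTNMILRGDGGILERSTDGYCPAPELLG
>FC2_SYNTH synthetic Fc/2 template, C-terminal Lys removed (not a natural sequence)
GPSVFLFPAKAGNFQRLPMGRRLLALAPTVCSHSQWLYALDYMLLFSGKQSPESGKDGRM
GFTEAVKMMLTNGSETKLRIKQVKVNNERSGECASREAIIGLTTVSYQDGVYIFGRKLVL
DVFLGLFVKNADSVELAVGLCKERSSRDFQEETKQQGAADFAYWYLCCASRNDKASLKQI
LTMDICPPSHLMRVTSKIPWLKESLSLSPG
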