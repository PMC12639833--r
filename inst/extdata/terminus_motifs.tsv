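class	motif
LC-START	DIQMTQSP
LC-START	EIVLTQSP
LC-START	QSVLTQPP
LC-END	KSFNRGEC
LC-END	TVAPTECS
Fd-START	EVQLVESG
Fd-START	QVQLVQSG
Fd-END	CPAPELLG
Fc/2-START	GPSVFLFP
Fc/2-END	SLSLSPG
Fc/2-END	LSLSPGK
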