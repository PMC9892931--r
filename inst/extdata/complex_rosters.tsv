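complex_id	name	subunits
BORC	BLOC-1-related complex	BLOC1S1;BLOC1S2;SNAPIN;LOH12CR1;KXD1;C10ORF32;C17ORF59;MEF2BNB
CCC	CCC (Commander) complex	COMMD2;COMMD3;COMMD4;COMMD5;COMMD8;COMMD10;CCDC22;CCDC93;VPS29;C16ORF62
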