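family	gene	sex	a1_cdna	a1_protein	a1_method	a1_ref	a2_cdna	a2_protein	a2_method	a2_ref	segregation
RP-1147	CNGA1	U	c.94C>T	p.Arg32*	aC	Paloma (2002)	c.830G>A	p.Arg277Gln	H	This study	Yes
RP-2066	PDE6A	U	c.1705C>A	p.Gln569Lys	aC	Dryja (1999)	c.1620+1G>T	splicing defect	H	This study	NA
RP-2114	RDH12	U	c.278T>C	p.Leu93Pro	aC	Avila-Fernandez (2010)	c.210-211insC	p.Arg71Glnfs*12	H	This study	NA
RP-1319	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.920-923dupGCCA	p.His308Glnfs*16	H	Weston (2000)	NA
RP-1412	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.1214delA	p.Asn405Ilefs*3	H	Schwartz (2005)	Yes
RP-1646	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.12575G>A	p.Arg4192His	H	Avila-Fernandez (2010)	Yes
RP-1695	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.9799T>C	p.Cys3267Arg	H	Aller (2006)	NA
RP-1735	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.12153-12175delAATTTTAAGCCCTTGGACTCTGA	p.Glu4051Aspfs*40	H	This study	NA
RP-1802	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.920-923dupGCCA	p.His308Glnfs*16	H	Weston (2000)	Yes
RP-1976	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.8254G>A	p.Gly2752Arg	H	Nakanishi (2009)	NA
RP-1979	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.1606T>C	p.Cys536Arg	H	Dreyer (2000)	Yes
RP-2112	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	Deletion Ex.45-49	-	H	Baux (2014)	NA
RP-2113	USH2A	U	c.2276G>T	p.Cys759Phe	aC	Rivolta (2000)	c.5462A>G	p.Lys1821Arg	H	This study	Yes
RP-1543	ABCA4	U	c.4234C>T	p.Gln1412*	H	Maugeri (1999)	c.5917delG	p.Val1973*	H	Rivera (2000)	NA
RP-1056	CERKL	U	c.847C>T	p.Arg283*	H	Tuson (2004)	c.664C>T	p.Gln222*	H	This study	Yes
RP-1998	CNGB1	U	c.2957A>T	p.Asn986Ile	H	Simpson (2011)	c.2957A>T	p.Asn986Ile	H	Simpson (2011)	Yes
RP-1706	EYS	U	c.2826-2827delAT	p.Val944Glyfs*9	H	This study	Deletion Ex.19	-	H	This study	Yes
RP-1929	EYS	U	c.9142dupA	p.Arg3048Lysfs*9	H	This study	Deletion Ex.13-14	-	H	Pieras (2011)	NA
RP-1142	GUCY2D	U	c.1762C>T	p.Arg588Trp	H	Stone (2007)	c.1762C>T	p.Arg588Trp	H	Stone (2007)	Yes
RP-0372	PDE6A	U	c.1957C>T	p.Arg653*	H	This study	c.1957C>T	p.Arg653*	H	This study	Yes
RP-0040	PRCD	U	c.74+1G>A	splicing defect	H	This study	c.74+1G>A	splicing defect	H	This study	Yes
RP-1772	RP1	U	c.2431delA	p.Ser812Valfs*36	H	This study					Yes
RP-1988	RP1	U	c.400-401insGC	p.His136Argfs*8	H	This study	c.400-401insGC	p.His136Argfs*8	H	This study	Yes
RP-1201	RP2	M	c.708C>G	p.Cys236Trp	H	This study					Yes
RP-0338	USH2A	U	c.9433C>T	p.Leu3145Phe	H	This study	c.9433C>T	p.Leu3145Phe	H	This study	Yes
RP-0344	USH2A	U	c.8693A>C	p.Tyr2898Ser	H	de Castro-Miro (2014)	c.10008C>A	p.Cys3336*	H	This study	Yes
RP-0456	USH2A	U	c.2276G>T	p.Cys759Phe	H	Rivolta (2000)	c.10709G>T	p.Cys3570Phe	H	This study	NA
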