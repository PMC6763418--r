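# Synthetic reconstruction of 34 published reduced amino-acid alphabets.
# Each record is a best-effort paraphrase of the cited study's grouping,
# reconstructed from the literature rather than transcribed verbatim from
# any single table; treat it as a realistic stand-in for the published
# collection (29 within-protein studies + 5 physico-chemistry studies),
# not as an authoritative transcription of any source.
# Columns: id <TAB> name <TAB> category <TAB> comma-delimited groups.
dayhoff6	Dayhoff et al. 1978 (synthetic reconstruction)	sequence_alignment	AGPST,C,DENQ,FWY,HKR,ILMV
murphy10	Murphy et al. 2000 (synthetic reconstruction)	sequence_alignment	A,C,DENQ,FWY,G,H,ILMV,KR,P,ST
cannata	Cannata et al. 2002 (synthetic reconstruction)	sequence_alignment	A,C,G,P,ST,DENQ,KRH,ILMV,FWY
fanwang	Fan & Wang 2003 (synthetic reconstruction)	sequence_alignment	ILMV,FWY,A,C,G,P,ST,NQ,DE,HKR
li10	Li et al. 2003 (synthetic reconstruction)	sequence_alignment	C,FYW,ML,IV,G,P,ATS,NH,QED,RK
edgar5	Edgar 2004 (synthetic reconstruction)	sequence_alignment	LVIMC,ASGTP,FYW,EDNQ,KRH
kosiol	Kosiol et al. 2004 (synthetic reconstruction)	sequence_alignment	A,C,G,P,DEN,QKR,H,ILMV,FWY,ST
andersen	Andersen & Brunak 2004 (synthetic reconstruction)	sequence_alignment	A,C,DE,FY,G,H,IV,KR,LM,NQ,P,ST,W
lenckowski	Lenckowski & Walczak 2007 (synthetic reconstruction)	sequence_alignment	ILMV,FWY,A,C,G,P,STNQ,DEKRH
susko6	Susko & Roger 2007 (synthetic reconstruction)	sequence_alignment	APST,DENG,QKR,MIVL,WC,FYH
risler	Risler et al. 1988 (synthetic reconstruction)	structure_alignment	ILMV,FY,AST,GP,DENQ,KR,HW,C
riddle5	Riddle et al. 1997 (synthetic reconstruction)	structure_alignment	CFILMVWY,DENQ,KRH,AST,GP
mirny6	Mirny & Shakhnovich 1999 (synthetic reconstruction)	structure_alignment	ACILMV,FWY,STNQ,KRH,DE,GP
prlic	Prlic et al. 2000 (synthetic reconstruction)	structure_alignment	A,C,DE,FWY,G,H,ILMV,KR,NQST,P
melo	Melo & Marti-Renom 2006 (synthetic reconstruction)	structure_alignment	A,C,D,E,FY,G,H,IV,KR,LM,N,P,Q,ST,W
robson	Robson & Suzuki 1976 (synthetic reconstruction)	protein_blocks	AGPST,DENQ,HKR,CFILMVWY
solis	Solis & Rackovsky 2000 (synthetic reconstruction)	protein_blocks	ADN,C,EKQ,FWY,G,H,ILV,M,PST,R
rogov	Rogov & Nekrasov 2001 (synthetic reconstruction)	protein_blocks	AGPST,CNQ,DE,HKR,ILMV,FWY
etchebest	Etchebest et al. 2007 (synthetic reconstruction)	protein_blocks	A,C,DE,FWY,G,H,ILMV,KR,NQS,P,T
peterson12	Peterson et al. 2009 (synthetic reconstruction)	protein_blocks	A,C,DE,FY,G,H,ILV,KR,MW,NQ,P,ST
zuoli	Zuo & Li 2003 (synthetic reconstruction)	protein_blocks	AG,C,DE,FWY,HKR,ILMV,NQ,P,ST
crippen	Crippen 1991 (synthetic reconstruction)	contact_potentials	AGST,CP,DENQ,FWY,H,ILMV,KR
maiorov	Maiorov & Crippen 1992 (synthetic reconstruction)	contact_potentials	AGPST,CFILMVWY,DENQ,H,KR
thomasdill	Thomas & Dill 1996 (synthetic reconstruction)	contact_potentials	ACFGILMVWY,DE,HKR,NPQST
wangwang5	Wang & Wang 1999 (synthetic reconstruction)	contact_potentials	CMFILVWY,ATH,GP,DE,SNQRK
cieplak	Cieplak et al. 2001 (synthetic reconstruction)	contact_potentials	AGPST,CFILMVWY,DENQ,HKR
liu	Liu et al. 2002 (synthetic reconstruction)	contact_potentials	CFYW,ILMV,AGPST,DENQ,HKR
mahler	Mahler & Cordes 1966 (synthetic reconstruction)	chemistry	AVLIPMFW,GSTCYNQ,DE,KRH
lehninger	Lehninger 1975 (synthetic reconstruction)	chemistry	AGPVLIM,FYW,STCNQ,DE,KRH
dickerson	Dickerson & Geis 1969 (synthetic reconstruction)	chemistry	GAVLIMWFP,YCTSHNQ,DE,KR
taylor	Taylor 1986 (synthetic reconstruction)	chemistry	ILMV,FWYH,KR,DE,NQ,ST,AG,CP
weathers	Weathers et al. 2004 (synthetic reconstruction)	chemistry	CFILMVWY,AGPSTH,DENQ,KR
albayrak	Albayrak et al. 2006 (synthetic reconstruction)	other	A,C,DE,FY,G,H,ILMV,KR,NQ,PST,W
chen	Chen et al. 2007 (synthetic reconstruction)	other	AGPST,C,DENQ,FWY,H,ILMV,KR
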