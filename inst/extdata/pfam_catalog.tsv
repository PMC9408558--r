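# Curated catalog of ABC-related Pfam profiles: domain category (NBD/TMD/other),
# Pfam clan, and for TMD profiles the structural class their members exhibit.
# Best-effort transcription of the published clan/family -> structural-class
# mapping; accessions are editable. class_hint is empty for non-TMD entries.
accession	name	category	clan	class_hint
PF00005	ABC_tran	NBD	ABC_tran	
PF02463	SMC_N	NBD	ABC_tran	
PF13304	AAA_21	NBD	ABC_tran	
PF00664	ABC_membrane	TMD	ABC_membrane	Pgp-like
PF06472	ABC_membrane_2	TMD	ABC_membrane	Pgp-like
PF12911	ABC_membrane_3	TMD	ABC_membrane	Pgp-like
PF05992	SbmA_BacA	TMD	ABC_membrane	Pgp-like
PF01061	ABC2_membrane	TMD	ABC-2	ABCG2-like
PF12679	ABC2_membrane_2	TMD	ABC-2	ABCG2-like
PF12698	ABC2_membrane_3	TMD	ABC-2	ABCG2-like
PF12730	ABC2_membrane_4	TMD	ABC-2	ABCG2-like
PF13346	ABC2_membrane_5	TMD	ABC-2	ABCG2-like
PF01903	CbiX	other	ABC-2	
PF03379	CcmB	TMD	ABC-2	ABCG2-like
PF12051	DUF3533	TMD	ABC-2	ABCG2-like
PF06422	PDR_CDR	other	ABC-2	
PF02588	YitT_membrane	other	ABC-2	
PF02687	FtsX	TMD	BPD_transp_1	MacB-like
PF00528	BPD_transp_1	TMD	BPD_transp_1	MalFG-like
PF07249	DUF1430	other	BPD_transp_1	
PF03739	YjgP_YjgQ	TMD	BPD_transp_1	LptFG-like
PF01032	FecCD	TMD	Membrane_trans	BtuCD-like
PF00950	ABC-3	TMD	Membrane_trans	BtuCD-like
PF12822	ECF_trnsprt	TMD	Gx_transp	EcfT-like
PF02361	CbiQ	TMD	none	EcfT-like
PF02405	MlaE	TMD	none	MlaE-like
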