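complement_activation	complement activation pathway members of the composite prognostic signature	CFB	IGHA1	IGHG	IGHG2	IGHG4	IGHM
ecm_remodelling	extracellular matrix remodelling members of the composite prognostic signature	COL6A2	MMP1	SPP1	TNC	P3H3
humoural_immune_response	humoural immune response members of the composite prognostic signature	BPIFA1	CXCL1	CXCL3	CXCL5	CXCL8	DMBT1
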