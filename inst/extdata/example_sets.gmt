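ADAPTOR_SIGNALING	toy signalling module	GRB2	CRK	SOS1	SHC1
AP1_COMPLEX	toy transcription module	JUN	FOS	FOSB	JUND
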