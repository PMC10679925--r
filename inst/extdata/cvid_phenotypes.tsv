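patient	sex	category
S1	male	SJOGREN
S2	female	PSORIATIC_ARTHRITIS
S3	female	SJOGREN
S4	female	UCTD
F1	female	SLE
F2	male	NECROTIZING_LYMPHADENITIS
F3	female	EGPA
F4	female	INFLAMMATORY_ARTHRITIS
F5	female	SLE
F6	female	SLE
F7	male	SLE
F8	female	SLE
F9	female	INFLAMMATORY_ARTHRITIS
F10	male	ITP
F11	male	PANCYTOPENIA
F12	male	SLE
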