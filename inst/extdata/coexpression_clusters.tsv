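condition	cluster	gene
treated-inactive	1	TLR1
treated-inactive	1	TLR2
treated-inactive	1	TLR4
treated-inactive	1	TLR6
treated-inactive	1	TLR8
treated-inactive	1	BCL6
treated-inactive	1	NR4A1
treated-inactive	1	NFKBIA
treated-inactive	1	LAG3
treated-inactive	1	HAVCR2
treated-inactive	1	TIGIT
treated-inactive	1	PDCD1
treated-inactive	1	CD40
treated-inactive	2	TRA
treated-inactive	2	CD40LG
treated-inactive	2	CTLA4
treated-inactive	2	PDCD1LG2
treated-inactive	2	CD28
treated-inactive	2	FOXP3
treated-active	1	CD274
treated-active	1	LAG3
treated-active	1	RELA
treated-active	1	PDCD1
treated-active	1	CD247
treated-active	1	TRA
treated-active	1	CD40LG
treated-active	1	CD28
treated-active	1	GATA3
treated-active	1	CTLA4
treated-active	1	FOXP3
treated-active	1	TBX21
treated-active	1	CCL5
treated-active	1	RORC
treated-active	2	NFKB1
treated-active	2	HAVCR2
treated-active	2	TIGIT
treated-active	2	NFKBIA
treated-active	2	CD83
treated-active	2	TNF
treated-active	2	NR4A1
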