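individual_id	cohort	variant_id
H01	HHDL	-1487A>G
H01	HHDL	-1080G>T
H02	HHDL	-1234C>T
H02	HHDL	-324A>G
H03	HHDL	-1487A>G
H03	HHDL	-303A>G
H04	HHDL	-1324C>T
H05	HHDL	-1080G>T
H06	HHDL	-1080G>T
H07	HHDL	-612C>A
H08	HHDL	-537T>C
H09	HHDL	-410C>G
H10	HHDL	-403C>G
H11	HHDL	-403C>G
H12	HHDL	-274C>T
H13	HHDL	-274C>T
H14	HHDL	-19A>G
H15	HHDL	-324A>G
H16	HHDL	-324A>G
L01	LHDL	-1666G>C
L02	LHDL	-1666G>C
L03	LHDL	-1223A>G
L04	LHDL	-1052C>A
L05	LHDL	-175G>A
L06	LHDL	44T>C
L07	LHDL	-324A>G
L08	LHDL	-303A>G
L09	LHDL	-303A>G
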