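variant_id	direction	relative_activity	p_value
-1487A>G	decrease	0.55	0.002
-1080G>T	decrease	0.60	0.004
-537T>C	decrease	0.50	0.001
-410C>G	decrease	0.65	0.008
-1666G>C	increase	1.60	0.003
-1223A>G	increase	1.50	0.006
-1052C>A	increase	1.45	0.009
-175G>A	increase	1.55	0.004
-303A>G	increase	1.40	0.012
-1324C>T	null	1.05	0.62
-1234C>T	null	0.95	0.48
-612C>A	null	1.02	0.81
-403C>G	null	0.97	0.55
-274C>T	null	1.08	0.33
-19A>G	null	0.99	0.90
44T>C	null	1.03	0.70
-324A>G	null	0.94	0.41
rs34474737	decrease	0.70	0.006
-1358insT	null	0.96	0.52
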