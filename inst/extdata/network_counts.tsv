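quantity	value
core_lags_total	555
core_lags_in_interactome	218
wln_core_retained	205
wln_partners	666
wln_total_genes	871
wln_essential_candidates	228
wln_clone_available	190
hln_essential_candidates	272
hln_clone_available	227
shared_clone_available	43
essential_candidates_total	500
candidates_overlap	54
genes_screened	374
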