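category	synthetic_ffpe_like	synthetic_cpg_deamination	synthetic_flat	synthetic_transversion_rich	synthetic_tpc_biased
C>A	0.03	0.02	0.143	0.30	0.05
C>G	0.03	0.02	0.143	0.25	0.05
C>T	0.55	0.20	0.143	0.10	0.10
C>T_at_CpG	0.25	0.60	0.143	0.05	0.05
T>A	0.04	0.04	0.143	0.20	0.05
T>C	0.06	0.08	0.142	0.05	0.60
T>G	0.04	0.04	0.143	0.05	0.10
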