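# Example parameters for the two-state CpG-island HMM.
# a_plus / a_minus: P(next | prev) dinucleotide rows (A, C, G, T order,
# rows sum to 1); the '+' table is CG-enriched, the '-' table CG-depleted.
# q_pm: probability of leaving a CpG island per step; q_mp: of entering one.
a_plus:
  - [0.18, 0.27, 0.43, 0.12]
  - [0.17, 0.37, 0.27, 0.19]
  - [0.16, 0.34, 0.37, 0.13]
  - [0.08, 0.36, 0.38, 0.18]
a_minus:
  - [0.30, 0.20, 0.29, 0.21]
  - [0.32, 0.30, 0.08, 0.30]
  - [0.25, 0.25, 0.30, 0.20]
  - [0.18, 0.24, 0.29, 0.29]
q_pm: 0.05
q_mp: 0.01
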