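# Scoring rubric, Problem 2 (tauopathy).
# STK11 is LKB1; the rubric names the kinase by its assay panel identifier.
# CNS criterion: predicted CNS penetration = TPSA < 75 A^2.
problem: 2
thresholds:
  pro_bind_nM: 10000
  anti_avoid_nM: 30000
  novelty_tc: 0.4
  cns_tpsa: 75
bind_criteria:
  - targets: [AURKA]
    points: [5]
    starred: [true]
  - targets: [PAK1]
    points: [5]
    starred: [true]
  - targets: [FGFR1, STK11]
    points: [1, 3]
avoid_criteria:
  - targets: [PAK3]
    points: [3]
    starred: [true]
  - targets: [MAP3K7]
    points: [3]
    starred: [true]
  - targets: [PIK3CA]
    points: [1]
bonus:
  novelty: 2
  patent: 2
  druglike: 3
  cns: 3
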