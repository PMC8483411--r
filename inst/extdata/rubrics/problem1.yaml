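# Scoring rubric, Problem 1 (RET-driven cancer).
# Starred targets mark requirements; star handling is chosen at scoring time
# (star_mode). Thresholds: pro-target "binding" = hit at 10 uM; anti-target
# "avoidance" = no hit at 30 uM.
problem: 1
thresholds:
  pro_bind_nM: 10000
  anti_avoid_nM: 30000
  novelty_tc: 0.4
bind_criteria:
  - targets: [RET_M918T]
    points: [5]
  - targets: [BRAF, SRC, S6K]
    points: [1, 3, 9]
avoid_criteria:
  - targets: [MKNK1]
    points: [3]
    starred: [true]
  - targets: [TTK, ERK8, PDK1, PAK3]
    points: [1, 2, 3, 4]
bonus:
  novelty: 2
  patent: 2
  druglike: 3
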