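# Default PBMC gating hierarchy. Root `live` = all live cells.
# Relations: gte (at/above threshold), lt (below), within ([lo, hi) band).
# `key` names the threshold(s) looked up at gate time; it defaults to the
# marker name, so only grade gates (hi / dim bands) set it explicitly.
nodes:
  - name: t_cells
    parent: live
    predicates:
      - {marker: CD3, relation: gte}
  - name: cd4_t
    parent: t_cells
    predicates:
      - {marker: CD4, relation: gte}
      - {marker: CD8, relation: lt}
  - name: pr_cd4
    parent: cd4_t
    predicates:
      - {marker: CD69, relation: gte}
      - {marker: CD40L, relation: gte}
  - name: treg
    parent: cd4_t
    predicates:
      - {marker: CD25, relation: gte, key: CD25_hi}
      - {marker: CD127, relation: lt}
  - name: mem_teff_cd4
    parent: cd4_t
    predicates:
      - {marker: CD45RA, relation: lt}
      - {marker: CD127, relation: gte}
      - {marker: CD25, relation: within, key: [CD25, CD25_hi]}
  - name: naive_cd4
    parent: cd4_t
    predicates:
      - {marker: CD45RA, relation: gte}
      - {marker: CCR7, relation: gte}
      - {marker: CD69, relation: lt}
  - name: cd8_t
    parent: t_cells
    predicates:
      - {marker: CD8, relation: gte}
      - {marker: CD4, relation: lt}
  - name: pr_cd8
    parent: cd8_t
    predicates:
      - {marker: CD69, relation: gte}
  - name: naive_cd8
    parent: cd8_t
    predicates:
      - {marker: CD45RA, relation: gte}
      - {marker: CCR7, relation: gte}
  - name: cm_cd8
    parent: cd8_t
    predicates:
      - {marker: CD45RA, relation: lt}
      - {marker: CCR7, relation: gte}
  - name: em_cd8
    parent: cd8_t
    predicates:
      - {marker: CD45RA, relation: lt}
      - {marker: CCR7, relation: lt}
  - name: temra_cd8
    parent: cd8_t
    predicates:
      - {marker: CD45RA, relation: gte}
      - {marker: CCR7, relation: lt}
  - name: nkt
    parent: t_cells
    predicates:
      - {marker: CD56, relation: gte}
      - {marker: CD4, relation: lt}
      - {marker: CD8, relation: lt}
  - name: gd_t
    parent: t_cells
    predicates:
      - {marker: gdTCR, relation: gte}
  - name: naive_gd
    parent: gd_t
    predicates:
      - {marker: CD45RA, relation: gte}
      - {marker: CCR7, relation: gte}
  - name: non_t
    parent: live
    predicates:
      - {marker: CD3, relation: lt}
  - name: b_cells
    parent: non_t
    predicates:
      - {marker: CD19, relation: gte}
  - name: plasmablast
    parent: b_cells
    predicates:
      - {marker: CD27, relation: gte, key: CD27_hi}
      - {marker: CD38, relation: gte, key: CD38_hi}
      - {marker: HLADR, relation: gte}
  - name: memory_b
    parent: b_cells
    predicates:
      - {marker: CD27, relation: within, key: [CD27, CD27_hi]}
      - {marker: CD38, relation: within, key: [CD38, CD38_hi]}
      - {marker: HLADR, relation: gte}
  - name: monocytes
    parent: non_t
    predicates:
      - {marker: CD14, relation: gte}
      - {marker: HLADR, relation: gte}
  - name: classical_mono
    parent: monocytes
    predicates:
      - {marker: CD16, relation: lt}
  - name: intermediate_mono
    parent: monocytes
    predicates:
      - {marker: CD16, relation: gte}
  - name: dc
    parent: non_t
    predicates:
      - {marker: CD14, relation: lt}
      - {marker: CD19, relation: lt}
      - {marker: HLADR, relation: gte}
      - {marker: CD11c, relation: gte}
  - name: mdc1
    parent: dc
    predicates:
      - {marker: CD123, relation: gte}
  - name: mdc2
    parent: dc
    predicates:
      - {marker: CD123, relation: lt}
  - name: nk_dim
    parent: non_t
    predicates:
      - {marker: CD56, relation: within, key: [CD56, CD56_hi]}
      - {marker: CD16, relation: gte}
      - {marker: CD19, relation: lt}
      - {marker: CD14, relation: lt}
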