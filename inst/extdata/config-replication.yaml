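# Replication configuration: the printed parameter values of the
# psoriasis communicative-gene workflow. Point the input paths at a
# normalized log2 expression study and a STRING-dialect edge list.
exprPath: expression.tsv
designPath: design.tsv
probeMapPath: probe_map.tsv
edgesPath: edges.tsv
degCutoffs:
  pMax: 0.01        # p-value < 0.01 (strict)
  fdrMax: 0.01      # adjusted p-value (FDR) < 0.01 (strict)
  minAbsLogfc: 1    # |logFC| >= 1 (inclusive)
  topN: 2000
minScore: 0.4       # minimum combined interaction score
primaryThresholds:  # whole-network micro-level thresholds (union rule)
  degree: 50
  stress: 200000
  eigenvector: 0.05
resolution: 1
seed: 0
relVarMin: 0.05
moduleThresholds:   # per-module top-gene thresholds, module-id order
  - degree: 87      # module 1
    stress: 8732
    betweenness: 0.03
  - degree: 26      # module 2
    eigenvector: 0.007
    stress: 8518
    betweenness: 0.04
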