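# Annotated run configuration for CrossRankNoN.
# Every key is optional; omitted keys take the defaults shown here.

# Prioritization method: cr (network of networks), crstar (star model with
# a scalar auxiliary coupling) or wcrstar (learned auxiliary weights).
method: cr

# For runLoocv: evaluate several methods and report paired t-tests between
# the first two.
# methods: [cr, crstar]

# Bundle directory (written by the simulate command or by writeBundle()).
# bundle: path/to/bundle

hyperparams:
  c: 0.85        # smoothness vs seed preference, as in personalized PageRank
  beta: 0.5      # cross-disease consistency weight
  alpha: 0.3     # center-auxiliary coupling (scalar star model)
  gamma: 1.0     # l2 penalty on learned auxiliary weights (wcrstar)
  tol: 1.0e-9    # fixed-point stopping tolerance (relative L-inf change)
  maxIter: 1000

# Truncation points of the ROC area used by the evaluation commands.
kList: [50, 100, 300, 500, 700, 1000]

# Seed for every source of randomness (simulation only; solvers are
# deterministic).
seed: 17

# Parameters of the synthetic benchmark generator (simulate command).
simulate:
  h: 20              # diseases
  n: 200             # genes per molecular network
  overlapFrac: 0.5   # expected shared-gene fraction between two diseases
  moduleSize: 10     # planted disease-module size
  seedsPerDisease: 3 # known disease genes per disease
  pIn: 0.3           # within-module edge probability
  pOut: 0.02         # background edge probability
  knnK: 5            # neighbors of the disease similarity kNN graph
  # auxNoise: [0.0, 1.0]  # per-auxiliary noise levels -> star bundle

# Temporal-split evaluation inputs (two-column TSV, no header).
# trainAssociations: train.tsv
# testAssociations: test.tsv
# maskKnown: false
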