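# Default pipeline configuration: an island-scale synthetic surveillance run.
# All coordinates are planar meters; one global seed drives every stage
# through fixed per-stage substreams.
seed: 20160801
extent: [0, 11600, 0, 11400]        # ~132 km^2 island
grid:
  cell_size: 200                    # surveillance cell side (m)
generator:
  n_patches: 400
  change_fraction: 0.107            # area fraction changing category A -> B
  road_spacing: 800                 # road lattice spacing (m)
  road_halfwidth: 12                # transportation strip half-width (m)
  shares:                           # year-A patch-category area shares
    natural: 0.522                  # (transportation land is the road strip)
    artificial: 0.104
    agriculture: 0.211
  dev_fraction: 0.616               # changed area drawn from natural -> development
  tubes_per_cell: 2
  jitter: 20                        # wave-2 relocation bound (m)
truth:
  beta0_or: 1.547                   # intercept, odds scale
  or:                               # category odds ratios vs natural
    artificial: 1.251
    transportation: 1.346
    agriculture: 2.247
    change: 1.354
  dist_effect:                      # per-category nonlinear distance effects
    transportation: {type: exp_decay, a: 1.2, scale: 200}
    change: {type: exp_decay, a: 0.9, scale: 120}
  spatial:
    type: gauss_bump
    amp: 1.0
    cx: 3000
    cy: 8500
    scale: 2500
model:
  k_dist: 10                        # distance-smooth basis dimension
  k_spatial: 6                      # marginal spatial basis dimension
out_dir: out
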