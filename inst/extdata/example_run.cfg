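# Minimal end-to-end run: simulate a two-population dataset, QC it, and
# compute windowed diversity/differentiation. Paths are relative to the
# output directory passed to runStage().
simulate.model = m11_ss_noflow
simulate.pops = north:12,south:12
simulate.L = 1000000
simulate.theta_site = 0.003
filter.min_maf = 0.05
filter.max_missing = 0.2
diversity.window_size = 100000
diversity.step = 10000
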