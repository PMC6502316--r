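# Shared domain-plan templates covering all nine domain types and all
# twelve subfamily subsets. Geometries are kept in realistic envelopes
# (Z2 spacing 9, dispersed linkers >= 12) so that decoy-free rendering
# guarantees oracle-exact recovery.

subset_templates <- function() {
  list(
    t1_QQQ   = list(specs = list(zf_spec("Q"), zf_spec("Q"), zf_spec("Q")),
                    linkers = c(5L, 8L)),
    t1_MQ    = list(specs = list(zf_spec("M1"), zf_spec("Q")),
                    linkers = 11L),
    t2_nine  = list(specs = c(list(zf_spec("Q"), zf_spec("M1"),
                                   zf_spec("M2"), zf_spec("M3"),
                                   zf_spec("M4"), zf_spec("M5")),
                              list(zf_spec("Q"), zf_spec("Q"),
                                   zf_spec("Q"))),
                    linkers = rep(5L, 8L)),
    i1_Q     = list(specs = list(zf_spec("Q")), linkers = integer(0)),
    i1_M     = list(specs = list(zf_spec("M3")), linkers = integer(0)),
    i1_Z1    = list(specs = list(zf_spec("Z1", ch_spacing = 20L)),
                    linkers = integer(0)),
    i1_Z2    = list(specs = list(zf_spec("Z2", ch_spacing = 9L)),
                    linkers = integer(0)),
    i1_D     = list(specs = list(zf_spec("D")), linkers = integer(0)),
    i2_Q     = list(specs = list(zf_spec("Q"), zf_spec("Q")),
                    linkers = 20L),
    i2_M     = list(specs = list(zf_spec("M1"), zf_spec("M4")),
                    linkers = 25L),
    i2_Z     = list(specs = list(zf_spec("Z1", ch_spacing = 20L),
                                 zf_spec("Z2", ch_spacing = 9L)),
                    linkers = 30L),
    i2_mix   = list(specs = list(zf_spec("Q"), zf_spec("M2")),
                    linkers = 20L),
    i2_mixD  = list(specs = list(zf_spec("Z1", ch_spacing = 20L),
                                 zf_spec("D")),
                    linkers = 15L),
    i3       = list(specs = list(zf_spec("Q"),
                                 zf_spec("Z1", ch_spacing = 20L),
                                 zf_spec("M1")),
                    linkers = c(15L, 14L)),
    i4       = list(specs = list(zf_spec("Q"), zf_spec("M2"),
                                 zf_spec("Z2", ch_spacing = 9L),
                                 zf_spec("Q")),
                    linkers = c(12L, 13L, 14L))
  )
}

# A decoy-free proteome of n proteins cycling through the templates.
full_coverage_proteome <- function(n = 200L, seed = 1L) {
  tpl <- subset_templates()
  idx <- rep(seq_along(tpl), length.out = n)
  simulate_proteome(
    domain_plan = lapply(idx, function(i) tpl[[i]]$specs),
    linker_lengths = lapply(idx, function(i) tpl[[i]]$linkers),
    seed = seed)
}
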