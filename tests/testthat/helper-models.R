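# Reference configurations: the enterobacterial mutation-accumulation setup
# (4 Mb start, ldel/dup rates 3.778e-9 per bp, indel rates twice that,
# indels uniform on 1..40 bp).
ref_rates <- function() mutation_rates()
ref_indels <- function() indel_model()
unif_rearr <- function() rearrangement_model("uniform")
lnorm_rearr <- function() rearrangement_model("truncated_lognormal")

# Rate set scaled up so that the stationary bulk sits at small sizes inside
# a few-hundred-state window (same 2:2:1:1 rate structure as the reference).
scaled_rates <- function() mutation_rates(0.04, 0.04, 0.02, 0.02)

# Chains are expensive to build; share them across test files.
.chain_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.chain_cache[[key]])) .chain_cache[[key]] <- force(expr)
  .chain_cache[[key]]
}
scaled_mg <- function(s_max) {
  cached(paste0("mg", s_max),
         build_mg(s_max, scaled_rates(), ref_indels(), unif_rearr()))
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# empirical size distribution over 1..s_max from long single-line runs,
# burn-in discarded; sizes above the window are clamped into the top bin
# (their mass is part of the TV discrepancy being measured)
empirical_size_dist <- function(s_max, n_lines, gens, burnin, rates, indels,
                                rearr) {
  sz <- unlist(lapply(seq_len(n_lines), function(i)
    run_line(100, gens, rates, indels, rearr)$sizes[-seq_len(burnin)]))
  tabulate(pmin(sz, s_max), s_max) / length(sz)
}
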