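# Deterministic per-iteration flop accounting for each update rule. Counts
# the multiply operations of the matrix products the update actually
# performs (precomputation excluded); used to verify the advertised
# complexity families as ratios across problem sizes, never as wall-clock
# claims.

#' Per-iteration flop count of a fitting update
#'
#' Multiplication counts of the matrix products each algorithm performs per
#' iteration, with precomputed quantities excluded. Leading terms:
#' SIC grows as (m+n)^2 N; Fast-SIC as nmN + n^2 N; aFast-SIC as
#' (n+m)N + n^2 N; POIC and the E-POIC family as nN.
#'
#' @param algorithm one of `"sic"`, `"fast_sic"`, `"afast_sic"`, `"poic"`,
#'   `"epoic_v1"`, `"epoic_v2"`, `"epoic"`.
#' @param N reference-frame pixel count.
#' @param n shape parameter count.
#' @param m appearance parameter count.
#' @param C channel count (default 1).
#' @return numeric flop count.
#' @export
update_flops <- function(algorithm = c("sic", "fast_sic", "afast_sic", "poic",
                                       "epoic_v1", "epoic_v2", "epoic"),
                         N, n, m, C = 1) {
  algorithm <- match.arg(algorithm)
  Nt <- N * C
  switch(algorithm,
    sic = {
      m * n * Nt +            # assemble J(c)
      (m + n)^2 * Nt +        # H_sic = J_sic^T J_sic
      (m + n) * Nt +          # J_sic^T r
      (m + n)^3               # solve
    },
    fast_sic = {
      m * n * Nt +            # assemble J(c)
      2 * m * n * Nt +        # project: A^T J then A (A^T J)
      n^2 * Nt +              # H = J_f^T J_f
      n * Nt +                # J_f^T r
      n^3 +                   # solve
      (m + n) * Nt            # dc back-substitution
    },
    afast_sic = {
      m * Nt +                # A(c)
      2 * n * Nt +            # J from gradients of A(c)
      2 * m * Nt +            # P_A r
      n^2 * Nt +              # H = J^T J
      n * Nt +                # J^T (P_A r)
      n^3 +                   # solve
      (m + n) * Nt            # dc back-substitution
    },
    # project-out family: one NC x n matrix-vector product plus the solve
    poic = ,
    epoic_v1 = ,
    epoic_v2 = ,
    epoic = n * Nt + n^3
  )
}
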