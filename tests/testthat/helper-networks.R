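# Shared fixtures, built in code.

skin_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_network(ros_species())
    cache
  }
})

proton_y <- primary_yields("proton")

initial_state_of <- flashros:::initial_state

# Independent brute-force assembly of the mass-action derivative directly
# from the reaction table (string parsing only; shares no code with
# evaluate_rhs). Used as the oracle for the right-hand side.
brute_force_rhs <- function(network, state, rate, yields, rho_w = 1) {
  dyn <- network$dyn
  dy <- setNames(numeric(length(dyn)), dyn)
  dy[names(yields)] <- yields * 1e-6 * rho_w * rate
  pools <- network$pools
  conc <- function(nm) if (nm %in% dyn) state[[nm]] else pools[[nm]]
  rx <- network$reactions
  for (j in seq_len(nrow(rx))) {
    terms <- function(side) {
      if (is.na(side) || !nzchar(trimws(side))) return(character(0))
      unlist(lapply(trimws(strsplit(side, "+", fixed = TRUE)[[1]]),
                    function(tm) {
                      p <- strsplit(tm, " +")[[1]]
                      if (length(p) == 2) rep(p[2], as.integer(p[1])) else p
                    }))
    }
    re <- terms(rx$reactants[j]); pr <- terms(rx$products[j])
    r <- rx$k[j]
    if (rx$order[j] == 1) {
      r <- r * conc(re[1])
    } else {
      for (nm in re) r <- r * max(conc(nm), 0)
    }
    for (nm in re) if (nm %in% dyn) dy[nm] <- dy[nm] - r
    for (nm in pr) {
      nm2 <- if (nm == "L" && network$lh_routing == "alkyl") "R" else nm
      if (nm2 %in% dyn) dy[nm2] <- dy[nm2] + r
    }
  }
  dy
}
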