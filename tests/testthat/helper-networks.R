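# Shared fixture builders for the test suite (constructed in code, no files).

# birth-death: 0 -> S (rate a), S -> 0 (rate b)
bd_network <- function(a = 200, b = 1) {
  reaction_network("S", list(
    rxn(products = c(S = 1), rate = a),
    rxn(reactants = c(S = 1), rate = b)
  ))
}

# repressor-promoter binding pair DA + R <-> DR
binding_network <- function(kf = 16, kb = 1) {
  reaction_network(c("DA", "R", "DR"), list(
    rxn(c(DA = 1, R = 1), c(DR = 1), rate = kf, timescale = "fast"),
    rxn(c(DR = 1), c(DA = 1, R = 1), rate = kb, timescale = "fast")
  ))
}

# competitive double binding (gene site + decoy sites)
double_binding_network <- function(kfA = 2000, kbA = 100, kfD = 10000, kbD = 100) {
  reaction_network(c("P", "G0", "GA", "D", "DP"), list(
    rxn(c(G0 = 1, P = 1), c(GA = 1), rate = kfA, timescale = "fast"),
    rxn(c(GA = 1), c(G0 = 1, P = 1), rate = kbA, timescale = "fast"),
    rxn(c(D = 1, P = 1), c(DP = 1), rate = kfD, timescale = "fast"),
    rxn(c(DP = 1), c(D = 1, P = 1), rate = kbD, timescale = "fast")
  ))
}

# the fast feedforward module of the negative-feedback model (species
# E, F, Q, R; the protein count enters as the symbolic parameter XP)
ffmodule_network <- function() {
  reaction_network(c("E", "F", "Q", "R"), list(
    rxn(products = c(E = 1), rate = "aE", timescale = "fast"),
    rxn(reactants = c(E = 1), rate = "bE", timescale = "fast"),
    rxn(reactants = c(E = 1), products = c(E = 1, Q = 1), rate = "aQ*XP",
        timescale = "fast"),
    rxn(reactants = c(Q = 1), rate = "bQ", timescale = "fast"),
    rxn(products = c(F = 1), rate = "aF", timescale = "fast"),
    rxn(reactants = c(F = 1), rate = "bF", timescale = "fast"),
    rxn(reactants = c(Q = 1, F = 1), products = c(Q = 1, F = 1, R = 1),
        rate = "aR", timescale = "fast"),
    rxn(reactants = c(R = 1), rate = "bR", timescale = "fast")
  ), params = c("aE", "bE", "aQ", "bQ", "aF", "bF", "aR", "bR", "XP"))
}

ones8 <- list(aE = 1, bE = 1, aQ = 1, bQ = 1, aF = 1, bF = 1, aR = 1, bR = 1)

# fast pair of the feedforward cascade (S1, S3) with S2 symbolic
fastpair_network <- function() {
  reaction_network(c("S1", "S3"), list(
    rxn(products = c(S1 = 1), rate = "a1", timescale = "fast"),
    rxn(reactants = c(S1 = 1), rate = "b1", timescale = "fast"),
    rxn(reactants = c(S1 = 1), products = c(S1 = 1, S3 = 1), rate = "a3*X2",
        timescale = "fast"),
    rxn(reactants = c(S3 = 1), rate = "b3", timescale = "fast")
  ), params = c("a1", "b1", "a3", "b3", "X2"))
}

qn <- function(x) exactqss:::q_parse(x)
qstr <- function(x) exactqss:::q_to_str(x)
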