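# Shared fixture builders: everything is generated in code at test time.

# A small complete genotype matrix with line/marker ids.
toyCalls <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("L%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("M%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

# MaskedPanel with an explicit set of masked cell indices.
maskCells <- function(calls, maskedIdx, ref = character(0),
                      test = character(0)) {
  InbredImpute:::.newMaskedPanel(toyCalls(calls), maskedIdx,
                                 scenario = list(kind = "manual"),
                                 refLines = ref, testLines = test)
}

# Small calibrated panel: study-like marker spacing (2.25 cM) at reduced size.
smallSim <- function(seed, nLines = 371, nMarkers = 84, nChrom = 2) {
  simulatePanel(panelParams(nLines = nLines, nMarkers = nMarkers,
                            nChrom = nChrom,
                            mapLengthCM = 2.25 * nMarkers, seed = seed))
}

# Brute-force Li-Stephens dosage by exhaustive path enumeration: the
# independent oracle for the forward-backward implementation.
lsPathOracle <- function(H, obs, stay, eps) {
  K <- nrow(H); M <- ncol(H)
  emis <- matrix(1, K, M)
  for (m in which(!is.na(obs)))
    emis[, m] <- ifelse(H[, m] == obs[m], 1 - eps, eps)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  w <- apply(paths, 1, function(z) {
    pr <- (1 / K) * emis[z[1], 1]
    if (M > 1) for (m in 2:M) {
      s <- stay[m - 1]
      pr <- pr * (s * (z[m] == z[m - 1]) + (1 - s) / K) * emis[z[m], m]
    }
    pr
  })
  w <- w / sum(w)
  vapply(seq_len(M), function(m)
    sum(w * H[cbind(paths[, m], m)]), numeric(1))
}
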