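# Independent brute-force oracles used to cross-check the implementation.

# Step-up FDR adjustment written directly from the definition.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# AUC by exhaustive pair enumeration, ties counted one-half.
aucOracle <- function(x, y) {
  g <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  mean(g)
}

# U by exhaustive pair counting.
uOracle <- function(x, y) sum(outer(x, y, ">") + 0.5 * outer(x, y, "=="))

# QC cascade by enumeration of all (n-1)-ion subsets: accept on the full set;
# otherwise drop, in turn, each ion flagged as the unique interference
# candidate (observed/reference ratio above detectFactor times the trace
# median) and accept if both cosines clear the threshold on the remaining
# ions; otherwise below-LOD by the summed-light rule; otherwise unresolved.
cascadeOracle <- function(light, heavy, ref, threshold = 0.98,
                          lodCriterion = 0, detectFactor = 3, minIons = 4L) {
  cosv <- function(a, b) {
    if (all(a == 0)) return(0)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  n <- length(ref)
  if (cosv(light, ref) > threshold && cosv(heavy, ref) > threshold)
    return(list(status = "accepted", ions = seq_len(n)))
  if (n - 1L >= minIons) {
    cand <- integer(0)
    for (v in list(light, heavy)) {
      if (sum(v) > 0) {
        q <- v / ref
        cand <- union(cand, which(q > detectFactor * median(q)))
      }
    }
    if (length(cand) == 1L) {
      subsets <- utils::combn(n, n - 1L, simplify = FALSE)
      for (keep in subsets) {
        if (!identical(setdiff(seq_len(n), keep), cand)) next
        if (cosv(light[keep], ref[keep]) > threshold &&
            cosv(heavy[keep], ref[keep]) > threshold)
          return(list(status = "accepted_after_substitution", ions = keep))
      }
    }
  }
  if (sum(light) < lodCriterion || all(light == 0))
    return(list(status = "below_lod", ions = seq_len(n)))
  list(status = "unresolved", ions = seq_len(n))
}

# Small quickly-simulated cohort panels used across tests.
smallPanel <- function() {
  peptidePanel(data.frame(
    protein = c("PERM", "PERM", "SPIT1", "SPIT1", "NUL1", "NUL1"),
    peptide = c("PEP_A", "PEP_B", "PEP_C", "PEP_D", "PEP_E", "PEP_F"),
    tumor_q1 = c(0.56, 0.94, 0.33, 0.30, 0.4, 0.4),
    tumor_q3 = c(2.18, 4.00, 0.66, 0.55, 1.2, 1.2),
    control_q1 = c(0.04, 0.08, 0.07, 0.06, 0.4, 0.4),
    control_q3 = c(0.13, 0.29, 0.20, 0.18, 1.2, 1.2)))
}

quietPipeline <- function(...) suppressWarnings(suppressMessages(runPipeline(...)))
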