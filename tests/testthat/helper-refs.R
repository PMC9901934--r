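# Small in-code references used across tests.

# 10-nt toy with one 3-bp stem and a leader.
toy_ref <- function() {
  ribozyme_reference(
    name = "toy",
    sequence = "GGCAUAGCCA",           # pairs (0,8) G:C, (1,7) G:C, (2,6) C:G
    leader = "GGAU",
    paired_regions = parse_structure("(((...)))." , "P1"),
    catalytic = 4L
  )
}

# Unstructured 4-nt reference from the interface examples.
acgu_ref <- function(leader = "GGAU") {
  ribozyme_reference(name = "acgu", sequence = "ACGU", leader = leader)
}

shipped_refs <- function() {
  lapply(c("cpeb3", "hdv", "twister", "hairpin", "hammerhead"),
         function(w) read_reference(ribodms_reference_file(w)))
}

# Brute-force sliding-window caller: every offset, plain mismatch count.
brute_call <- function(read, ref_seq, max_muts = 2) {
  L <- nchar(ref_seq)
  if (nchar(read) < L) return(list(reason = "short"))
  rch <- strsplit(read, "")[[1]]
  fch <- strsplit(ref_seq, "")[[1]]
  best <- L + 1; best_off <- NA
  for (off in 0:(nchar(read) - L)) {
    mm <- sum(rch[(off + 1):(off + L)] != fch)
    if (mm < best) { best <- mm; best_off <- off }
  }
  if (best > max_muts) return(list(reason = "too_many_mutations",
                                   mismatch = best))
  idx <- which(rch[(best_off + 1):(best_off + L)] != fch)
  g <- if (length(idx) == 0) "WT" else
    paste(sprintf("%d:%s", idx - 1L, rch[best_off + idx]), collapse = ",")
  list(reason = "ok", offset = best_off, mismatch = best, genotype = g)
}

# Brute-force Mann-Whitney: every assignment of pooled values to groups.
brute_mw <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  idx <- utils::combn(m + n, m)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                      mean(u_all >= u_obs - eps)))
  list(u = u_obs, p = p)
}
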