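# shared fixture builders and independent oracles

make_profiles <- function(ids, fun, csc, dsc_raw) {
  expression_profiles(ids, fun, csc, dsc_raw)
}

# n genes proportional to a base triple, ids generated on "chromosome 8"
proportional_profiles <- function(base, scales, prefix = 1L) {
  ids <- sprintf("At8g%05d", prefix * 100L + seq_along(scales))
  m <- t(vapply(scales, function(s) s * base, numeric(3)))
  expression_profiles(ids, m[, 1], m[, 2], m[, 3] * 26.8)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# --- independent clustering oracle -----------------------------------------
# Checks a greedy partition against the stated rule by exhaustive subset
# enumeration (feasible for <= ~10 genes): each emitted subgroup must (a)
# satisfy the all-pairs R2 >= r2_min constraint, (b) be maximal by inclusion
# among valid subsets of the genes still unassigned when it was seeded, and
# (c) be seeded by the lexicographically smallest unassigned gene.
check_partition_oracle <- function(subgroups, genes, r2, r2_min) {
  remaining <- sort(genes)
  valid_set <- function(mem) {
    if (length(mem) < 2L) return(TRUE)
    all(r2[mem, mem][upper.tri(r2[mem, mem])] >= r2_min)
  }
  for (sg in subgroups[order(vapply(subgroups, function(s) s$members[1],
                                    character(1)))]) {
    mem <- sg$members
    if (!identical(mem[1], remaining[1])) return(FALSE)   # seeding rule
    if (!all(mem %in% remaining)) return(FALSE)
    if (!valid_set(mem)) return(FALSE)                    # all-pairs constraint
    outside <- setdiff(remaining, mem)
    for (g in outside)                                    # maximality
      if (valid_set(c(mem, g))) return(FALSE)
    remaining <- outside
  }
  length(remaining) == 0L
}

random_triples <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(3 * n, 1, 100), ncol = 3)
  rownames(m) <- sprintf("At8g%05d", seq_len(n))
  colnames(m) <- c("fun", "csc", "dsc_norm")
  m
}
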