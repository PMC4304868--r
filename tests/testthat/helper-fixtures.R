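# Shared builders and independent oracles for the test suite.

# a small five-region locus (35 bp) used across tests
toy_locus <- function(seed = 1) {
  make_locus(c(`18S` = 10, ITS1 = 5, `5.8S` = 5, ITS2 = 5, `26S` = 10),
             seed = seed)
}

# dot-bracket structure lines matching toy_locus region lengths,
# with the 5.8S and 26S regions co-folded into one '&'-joined record
toy_structure_lines <- function() {
  c("18S",      "ACGTACGTAC",       "((......)) (-1.20)",
    "ITS1",     "ACGTA",            "..... (0.00)",
    "ITS2",     "ACGTA",            "(...) (-0.50)",
    "5.8S+26S", "ACGTA&ACGTACGTAC", "((..(&)..))..... (-2.00)")
}

# brute-force mismatch count of a read at one offset (N in read skipped;
# N in target never matches)
oracle_mismatches <- function(read, target, offset) {
  r <- strsplit(read, "")[[1]]
  t <- strsplit(substr(target, offset, offset + nchar(read) - 1L), "")[[1]]
  sum(r != "N" & (t == "N" | r != t))
}

# brute-force per-position recount of a polymorphism profile from simple
# (all-M) alignments, projected through a coordinate map
oracle_profile <- function(aln, L_cons, cm, th) {
  columns <- vector("list", L_cons)
  for (i in seq_len(nrow(aln))) {
    chars <- strsplit(aln$seq[i], "")[[1]]
    for (k in seq_along(chars)) {
      p <- aln$start[i] + k - 1L
      columns[[p]] <- c(columns[[p]], chars[k])
    }
  }
  status <- character(cm$ref_length)
  for (rp in seq_len(cm$ref_length)) {
    cp <- cm$ref_to_cons[rp]
    if (is.na(cp) || is.null(columns[[cp]])) { status[rp] <- "UNASSEMBLED"; next }
    t <- tally_column(columns[[cp]])
    status[rp] <- as.character(classify_site(t, th))
  }
  status
}

# numeric minimization oracle for squared-change parsimony
oracle_scp <- function(tree, values, weighted = FALSE) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  w <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  y <- values[tree$tip.label]
  obj <- function(x) {
    states <- c(unname(y), x)
    sum((states[tree$edge[, 1]] - states[tree$edge[, 2]])^2 / w)
  }
  fit <- optim(rep(mean(y), m), obj, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  list(node_states = fit$par, scp_length = fit$value)
}

# random bifurcating tree with uniform branch lengths
random_tree <- function(n_tips, seed) {
  set.seed(seed)
  ape::rtree(n_tips)
}
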