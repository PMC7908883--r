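# Independent brute-force oracles, deliberately written without reusing any
# package internals, used to check the fast implementations.

# nearest of the seven bias archetypes by explicit loop; ties resolved by
# the fixed archetype order
oracle_nearest_archetype <- function(rel) {
  arch <- list(
    balanced       = c(1, 1, 1) / 3,
    `A-dominant`   = c(1, 0, 0),
    `B-dominant`   = c(0, 1, 0),
    `D-dominant`   = c(0, 0, 1),
    `A-suppressed` = c(0, 0.5, 0.5),
    `B-suppressed` = c(0.5, 0, 0.5),
    `D-suppressed` = c(0.5, 0.5, 0)
  )
  best <- NULL; best_d <- Inf
  for (nm in names(arch)) {
    d <- sqrt(sum((rel - arch[[nm]])^2))
    if (d < best_d) { best <- nm; best_d <- d }
  }
  best
}

# position-by-position duplex penalty score; both sequences 5'->3', target
# window reversed here for antiparallel pairing; ungapped only
oracle_duplex_score <- function(mirna, window) {
  norm <- function(x) gsub("T", "U", toupper(x))
  mir <- strsplit(norm(mirna), "")[[1]]
  win <- rev(strsplit(norm(window), "")[[1]])
  stopifnot(length(mir) == length(win))
  total <- 0
  for (i in seq_along(mir)) {
    m <- mir[i]; t <- win[i]
    wc <- (m == "A" && t == "U") || (m == "U" && t == "A") ||
          (m == "G" && t == "C") || (m == "C" && t == "G")
    gu <- (m == "G" && t == "U") || (m == "U" && t == "G")
    pen <- if (wc) 0 else if (gu) 0.5 else 1
    if (i >= 2 && i <= 13) pen <- pen * 2
    total <- total + pen
  }
  total
}

# T-plot category by direct restatement of the rule table
oracle_tplot_category <- function(site_count, counts) {
  M <- max(counts)
  occupied <- counts[counts >= 1]
  med <- if (length(occupied)) stats::median(occupied) else NA
  if (site_count == 0) return("none")
  if (site_count == 1) return("4")
  if (site_count == M) {
    if (sum(counts == M) == 1) return("0") else return("1")
  }
  if (site_count > med) return("2")
  "3"
}

# pI by fine grid search on the net-charge curve
oracle_pi_grid <- function(sequence, step = 1e-3) {
  grid <- seq(0, 14, by = step)
  q <- polyfam::peptide_charge(sequence, grid)
  grid[which.min(abs(q))]
}

# simple random simplex points (uniform via normalized exponentials)
random_simplex <- function(n) {
  x <- matrix(stats::rexp(3 * n), ncol = 3)
  x / rowSums(x)
}

# a small in-memory ExpressionMatrix fixture
toy_expression_matrix <- function(values, tissues) {
  meta <- data.frame(sample_id = colnames(values),
                     tissue = tissues, stage = "s1", condition = "control",
                     tissue_class = ifelse(tissues %in% c("spikelet", "grain"),
                                           "reproductive",
                                           ifelse(tissues == "root", "root", "vegetative")))
  polyfam::expression_matrix(values, meta)
}
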