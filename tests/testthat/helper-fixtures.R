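# Small in-code fixtures shared across test files.

# Atlas with k ROIs per network, centers spread far apart on a coarse
# lattice so sphere masks never overlap.
toy_atlas <- function(k = c(CON = 2, DMN = 2, OST = 2), spacing = 40,
                      radius = 5) {
  rows <- do.call(rbind, lapply(seq_along(k), function(ni) {
    net <- names(k)[ni]
    data.frame(label = paste0(net, "_", seq_len(k[[ni]])),
               network = net,
               x = spacing * (seq_len(k[[ni]]) - 1) - 60,
               y = spacing * (ni - 2),
               z = 0,
               radius = radius, stringsAsFactors = FALSE)
  }))
  as_atlas(rows)
}

# Write an atlas data frame to a temp TSV and return the path.
write_atlas_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Cohort data frame with hand-set metric values and optional covariates;
# groups of equal size n_per.
toy_cohort <- function(n_per = 4, seed = 1, sd = 0.1,
                       means = c(OCD = 0.5, AC = 0.4, HC = 0.4),
                       age = TRUE) {
  set.seed(seed)
  g <- rep(names(means), each = n_per)
  out <- data.frame(subject_id = sprintf("s%02d", seq_along(g)),
                    group = factor(g, levels = names(means)),
                    stringsAsFactors = FALSE)
  if (age) {
    out$age <- runif(nrow(out), 8, 21)
    out$mean_fd <- rlnorm(nrow(out), -2, 0.4)
  }
  for (m in FCNET_METRICS)
    out[[m]] <- rnorm(nrow(out), means[g], sd)
  out
}

# Independent Pearson correlation oracle straight from the definition.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Literal Benjamini-Hochberg min-formula oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
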