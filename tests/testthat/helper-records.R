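# shared builders for specimen fixtures

# one record from named locus scores; unspecified loci stay unscored
make_record <- function(..., id = "r1", age = "adult") {
  vals <- list(...)
  df <- data.frame(specimen_id = id, age_class = age,
                   stringsAsFactors = FALSE)
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  as_wing_records(df)
}

bind_records <- function(...) {
  dfs <- lapply(list(...), as.data.frame)
  as_wing_records(do.call(rbind, dfs))
}

# random wing-chain records with mixed ages and occasional unscored loci
random_records <- function(n, seed, p_unscored = 0.1) {
  set.seed(seed)
  codes <- c(0.05, seq(0.1, 0.9, by = 0.1), 1, 2)
  prob <- c(rep(0.03, 10), 0.3, 0.4)
  rows <- lapply(seq_len(n), function(i) {
    s <- sample(codes, 21, replace = TRUE, prob = prob)
    s[stats::runif(21) < p_unscored] <- NA
    df <- data.frame(specimen_id = sprintf("rnd%03d", i),
                     age_class = "adult", stringsAsFactors = FALSE)
    for (k in seq_along(wing_chain())) df[[wing_chain()[k]]] <- s[k]
    df
  })
  as_wing_records(do.call(rbind, rows))
}

primary_series <- function(k = 10) molt_series("primaries", paste0("P", 1:k))
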