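# Small in-code fixtures shared across the test files.

make_records <- function(n, island = "Cuba", ecomorph = "trunk-ground",
                         species = "sp001", source = "museum",
                         treatment = NA_character_, sex = "male",
                         prefix = "s") {
  data.frame(specimen_id = sprintf("%s%03d", prefix, seq_len(n)),
             species = species, island = island, ecomorph = ecomorph,
             sex = sex, source = source, treatment = treatment,
             stringsAsFactors = FALSE)
}

# A tiny two-ecomorph, two-island design with given per-cell sizes and a
# known mean shift per cell; traits are iid normal around the cell mean.
make_quartet_data <- function(n_cell = 10L, p = 20L, shift = NULL,
                              seed = 1L) {
  set.seed(seed)
  cells <- expand.grid(ecomorph = c("trunk-ground", "trunk-crown"),
                       island = c("Cuba", "Jamaica"),
                       stringsAsFactors = FALSE)
  if (is.null(shift)) shift <- matrix(0, 4L, p)
  recs <- list()
  traits <- list()
  for (i in seq_len(nrow(cells))) {
    r <- make_records(n_cell, island = cells$island[i],
                      ecomorph = cells$ecomorph[i],
                      species = sprintf("sp_%d", i),
                      prefix = sprintf("c%d_", i))
    x <- matrix(rnorm(n_cell * p), n_cell, p) +
      matrix(rep(shift[i, ], each = n_cell), n_cell, p)
    rownames(x) <- r$specimen_id
    recs[[i]] <- r
    traits[[i]] <- x
  }
  records <- do.call(rbind, recs)
  x <- do.call(rbind, traits)
  colnames(x) <- sprintf("len_t%02d", seq_len(p))
  list(records = records, traits = x,
       quartet = data.frame(e1 = "trunk-crown", e2 = "trunk-ground",
                            i1 = "Cuba", i2 = "Jamaica",
                            stringsAsFactors = FALSE))
}

# Random landmark configuration around a template.
make_config <- function(template = NULL, noise = 0, structure = "pectoral",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(template)) template <- matrix(rnorm(54), 18L, 3L)
  landmark_configuration(template + matrix(rnorm(54, sd = noise), 18L, 3L),
                         structure = structure)
}

random_rotation3 <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}
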