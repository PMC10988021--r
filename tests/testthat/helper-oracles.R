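# Independent oracles, deliberately written without reference to the package
# internals: a recursive affine-gap alignment scorer, a linear-gap global
# scorer matching the MSA profile scoring on single sequences, an atomic
# composition mass calculator, and the textbook pooled-variance t statistic.

# Exhaustive affine-gap score by plain dynamic programming over three states.
# Gap of length L costs open + (L - 1) * ext. Returns the optimal score
# (local: best over all subpaths, floored at 0 per cell).
oracle_affine_score <- function(q, r, submat, open, ext, local = FALSE) {
  qa <- strsplit(q, "")[[1]]
  ra <- strsplit(r, "")[[1]]
  n <- length(qa); m <- length(ra)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (!local) {
    for (i in seq_len(n)) X[i + 1, 1] <- -open - (i - 1) * ext
    for (j in seq_len(m)) Y[1, j + 1] <- -open - (j - 1) * ext
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - ext)
    s <- submat[qa[i], ra[j]]
    v <- max(M[i, j], X[i, j], Y[i, j]) + s
    if (local) v <- max(v, 0)
    M[i + 1, j + 1] <- v
  }
  if (local) max(M) else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Global Needleman-Wunsch score with linear gaps (match/mismatch/gap), the
# degenerate single-sequence case of profile-profile alignment.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  aa <- strsplit(a, "")[[1]]
  bb <- strsplit(b, "")[[1]]
  n <- length(aa); m <- length(bb)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (aa[i] == bb[j]) match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap, D[i + 1, j] + gap)
  }
  D[n + 1, m + 1]
}

# Peptide average/monoisotopic mass from scratch: count atoms per residue and
# weigh them. Formulas are the free amino acids; the peptide loses one water
# per bond.
oracle_peptide_mass <- function(seq, mode = "average") {
  formulas <- list( # free amino acid C,H,N,O,S
    A = c(3, 7, 1, 2, 0), C = c(3, 7, 1, 2, 1), D = c(4, 7, 1, 4, 0),
    E = c(5, 9, 1, 4, 0), F = c(9, 11, 1, 2, 0), G = c(2, 5, 1, 2, 0),
    H = c(6, 9, 3, 2, 0), I = c(6, 13, 1, 2, 0), K = c(6, 14, 2, 2, 0),
    L = c(6, 13, 1, 2, 0), M = c(5, 11, 1, 2, 1), N = c(4, 8, 2, 3, 0),
    P = c(5, 9, 1, 2, 0), Q = c(5, 10, 2, 3, 0), R = c(6, 14, 4, 2, 0),
    S = c(3, 7, 1, 3, 0), T = c(4, 9, 1, 3, 0), V = c(5, 11, 1, 2, 0),
    W = c(11, 12, 2, 2, 0), Y = c(9, 11, 1, 3, 0))
  wts <- if (mode == "average") {
    c(12.011, 1.008, 14.007, 15.999, 32.06)
  } else {
    c(12, 1.0078250319, 14.0030740052, 15.9949146221, 31.97207069)
  }
  water <- c(0, 2, 0, 1, 0)
  aa <- strsplit(seq, "")[[1]]
  atoms <- Reduce(`+`, formulas[aa]) - (length(aa) - 1) * water
  sum(atoms * wts)
}

# Textbook pooled-variance two-sample t statistic and p-value.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Random protein of length n under a seed (test inputs only).
random_protein <- function(n, seed) {
  with_seed(seed, paste(sample(c("A","C","D","E","F","G","H","I","K","L","M",
                                 "N","P","Q","R","S","T","V","W","Y"),
                               n, replace = TRUE), collapse = ""))
}

# Intersection-over-union of two logical masks.
mask_iou <- function(a, b) sum(a & b) / sum(a | b)

# The 20-cell benchmark scene used by segmentation and colocalization tests.
twenty_cell_scene <- function(background = 5, psf_sigma = 0.08,
                              gaussian_sd = 0, poisson = FALSE, seed = 1L) {
  grid <- expand.grid(gx = 1:5, gy = 1:4)
  cells <- with_seed(4242, lapply(seq_len(20), function(k) {
    synth_cell(x = grid$gx[k] * 2.4 - 1.2, y = grid$gy[k] * 3.0 - 1.5,
               angle = runif(1, 0, pi), length = runif(1, 1.5, 3),
               width = runif(1, 0.6, 0.9), cyto = runif(1, 80, 120))
  }))
  cell_scene(cells, nx = 256, ny = 256, background = background,
             psf_sigma = psf_sigma, gaussian_sd = gaussian_sd,
             poisson = poisson, seed = seed)
}
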