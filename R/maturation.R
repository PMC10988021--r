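# Lanthipeptide maturation model: leader cleavage, Ser/Thr dehydration,
# lanthionine ring formation, N-terminal lactate, and mass prediction.
#
# All chemistry is explicit atomic-composition bookkeeping on the residue
# level (peptide mass = sum of residue compositions + one H2O for the
# termini):
#   * dehydration (Ser -> Dha, Thr -> Dhb): -H2O
#   * lanthionine formation (thioether Michael addition): no atom change
#     beyond the prior dehydration
#   * N-terminal lactate: the amine-bearing N-terminal Dha is hydrolyzed to a
#     pyruvyl group (+H2O, -NH3) and reduced to lactyl (+H2); net -N +H +O
#   * Abu (alpha-aminobutyrate from Thr): dehydration then reduction,
#     net -O relative to Thr
#   * methylation: +CH2 each

# residue compositions (amino acid minus water), C/H/N/O/S
AA_COMPOSITION <- matrix(c(
  # C   H  N  O  S
    3,  5, 1, 1, 0,  # A
    3,  5, 1, 1, 1,  # C
    4,  5, 1, 3, 0,  # D
    5,  7, 1, 3, 0,  # E
    9,  9, 1, 1, 0,  # F
    2,  3, 1, 1, 0,  # G
    6,  7, 3, 1, 0,  # H
    6, 11, 1, 1, 0,  # I
    6, 12, 2, 1, 0,  # K
    6, 11, 1, 1, 0,  # L
    5,  9, 1, 1, 1,  # M
    4,  6, 2, 2, 0,  # N
    5,  7, 1, 1, 0,  # P
    5,  8, 2, 2, 0,  # Q
    6, 12, 4, 1, 0,  # R
    3,  5, 1, 2, 0,  # S
    4,  7, 1, 2, 0,  # T
    5,  9, 1, 1, 0,  # V
   11, 10, 2, 1, 0,  # W
    9,  9, 1, 2, 0   # Y
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                    "R","S","T","V","W","Y"), c("C","H","N","O","S")))

ATOMIC_WEIGHT <- list(
  average = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06),
  monoisotopic = c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069))

WATER <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

#' Split a precursor into leader and core peptide
#'
#' @param precursor full precursor amino-acid sequence.
#' @param cleavage either an integer (cleave after this many residues) or a
#'   character motif; cleavage occurs immediately after the motif's last
#'   residue.
#' @return list with `sequence`, `leader`, `core`, `cleavage_pos`.
#' @export
cleave_leader <- function(precursor, cleavage) {
  assert_protein(precursor, "precursor")
  n <- nchar(precursor)
  if (is.numeric(cleavage)) {
    pos <- as.integer(cleavage)
    if (pos < 1L || pos >= n) stop("cleavage position must be in [1, length-1]")
  } else {
    hit <- regexpr(cleavage, precursor, fixed = TRUE)
    if (hit < 0) {
      # report near matches (single-mismatch candidates) to help diagnosis
      m <- nchar(cleavage)
      cand <- vapply(seq_len(n - m + 1L), function(i) {
        sum(strsplit(substr(precursor, i, i + m - 1L), "")[[1]] !=
              strsplit(cleavage, "")[[1]])
      }, numeric(1))
      near <- which(cand == min(cand))
      stop("cleavage motif '", cleavage, "' not found; closest candidates at ",
           "positions ", paste(head(near, 3), collapse = ", "),
           " (", min(cand), " mismatches)")
    }
    pos <- as.integer(hit) + nchar(cleavage) - 1L
    if (pos >= n) stop("motif ends at the last residue; core would be empty")
  }
  list(sequence = precursor,
       leader = substr(precursor, 1L, pos),
       core = substr(precursor, pos + 1L, n),
       cleavage_pos = pos)
}

#' Describe a set of posttranslational modifications
#'
#' Positions are 1-based within the core peptide.
#'
#' @param dehydrated integer positions of Ser/Thr dehydrated to Dha/Dhb.
#' @param rings data.frame or list of `c(donor, acceptor)` pairs (acceptor
#'   must be Cys); optionally a third element "Lan"/"MeLan" (otherwise
#'   derived from the donor residue: Ser -> Lan, Thr -> MeLan).
#' @param lactate logical; replace the N-terminal Dha with a lactyl cap
#'   (requires position 1 originally Ser and dehydrated).
#' @param abu integer positions of Thr reduced to alpha-aminobutyrate.
#' @param methylations non-negative integer count of CH2 additions.
#' @return a `modification_set` list.
#' @export
modification_set <- function(dehydrated = integer(), rings = list(),
                             lactate = FALSE, abu = integer(),
                             methylations = 0L) {
  rings <- lapply(rings, function(r) {
    list(donor = as.integer(r[[1]]), acceptor = as.integer(r[[2]]),
         type = if (length(r) >= 3) as.character(r[[3]]) else NA_character_)
  })
  if (methylations < 0) stop("methylations must be >= 0")
  structure(list(dehydrated = as.integer(dehydrated), rings = rings,
                 lactate = isTRUE(lactate), abu = as.integer(abu),
                 methylations = as.integer(methylations)),
            class = "modification_set")
}

#' The default modification set of the bundled synthetic epilancin core
#'
#' Carries the canonical epilancin topology on the 30-residue synthetic core:
#' N-terminal lactate, ring A (Lan 12-16), intertwined rings B (MeLan 20-23)
#' and C (Lan 21-24), one Abu at 27.
#'
#' @return a [modification_set()].
#' @export
ela_modifications <- function() {
  modification_set(dehydrated = c(1L, 3L, 8L, 12L, 20L, 21L),
                   rings = list(c(12, 16), c(20, 23), c(21, 24)),
                   lactate = TRUE, abu = 27L, methylations = 0L)
}

validate_mods <- function(core, mods) {
  aa <- strsplit(core, "")[[1]]
  n <- length(aa)
  if (any(mods$dehydrated < 1 | mods$dehydrated > n))
    stop("invalid modification: dehydrated position outside the core")
  if (!all(aa[mods$dehydrated] %in% c("S", "T")))
    stop("invalid modification: dehydrated positions must be Ser or Thr")
  acceptors <- vapply(mods$rings, `[[`, integer(1), "acceptor")
  if (anyDuplicated(acceptors))
    stop("invalid modification: a Cys is used in more than one ring")
  for (r in mods$rings) {
    if (r$donor >= r$acceptor)
      stop("invalid modification: ring donor must precede its acceptor")
    if (r$acceptor > n || aa[r$acceptor] != "C")
      stop("invalid modification: ring acceptor must be a core Cys")
    if (!(r$donor %in% mods$dehydrated))
      stop("invalid modification: ring donor must be a dehydrated Ser/Thr")
  }
  if (mods$lactate) {
    if (aa[1] != "S" || !(1L %in% mods$dehydrated))
      stop("invalid modification: N-terminal lactate requires position 1 to be a dehydrated Ser")
  }
  if (any(mods$abu < 1 | mods$abu > n) || !all(aa[mods$abu] == "T"))
    stop("invalid modification: Abu positions must be core Thr")
  invisible(TRUE)
}

#' Apply a modification set to a core peptide
#'
#' @param core core peptide amino-acid string.
#' @param mods a [modification_set()].
#' @return a `mature_peptide` list: per-residue labels, composition matrix,
#'   ring topology `segments`, and `average`/`monoisotopic` masses (Da).
#' @export
apply_maturation <- function(core, mods = modification_set()) {
  assert_protein(core, "core")
  validate_mods(core, mods)
  aa <- strsplit(core, "")[[1]]
  if (any(!aa %in% rownames(AA_COMPOSITION)))
    stop("unknown residue composition: ",
         paste(unique(aa[!aa %in% rownames(AA_COMPOSITION)]), collapse = ", "))
  comp <- AA_COMPOSITION[aa, , drop = FALSE]
  label <- aa
  for (p in mods$dehydrated) {
    comp[p, ] <- comp[p, ] - c(0, 2, 0, 1, 0) # -H2O
    label[p] <- if (aa[p] == "S") "Dha" else "Dhb"
  }
  for (r in mods$rings) {
    type <- if (!is.na(r$type)) r$type else if (aa[r$donor] == "S") "Lan" else "MeLan"
    label[r$donor] <- paste0(type, "-donor")
    label[r$acceptor] <- paste0(type, "-acceptor")
    # thioether addition: no atomic change beyond the prior dehydration
  }
  if (mods$lactate) {
    comp[1, ] <- comp[1, ] + c(0, 1, -1, 1, 0) # Dha -> lactyl: -N +H +O
    label[1] <- "Lac"
  }
  for (p in mods$abu) {
    comp[p, ] <- comp[p, ] - c(0, 0, 0, 1, 0) # Thr -> Abu: net -O
    label[p] <- "Abu"
  }
  extra <- c(C = 1, H = 2, N = 0, O = 0, S = 0) * mods$methylations
  segs <- ring_segments(nchar(core), mods$rings)
  obj <- structure(list(core = core, residues = label, composition = comp,
                        extra = extra, mods = mods, segments = segs),
                   class = "mature_peptide")
  obj$average <- peptide_mass(obj, "average")
  obj$monoisotopic <- peptide_mass(obj, "monoisotopic")
  obj
}

# Ring topology segments: linear N-terminus, then alternating ring-system
# spans (overlapping rings merged into one intertwined system) and linear
# hinges, then the C-terminal tail. Lengths sum to the core length; residues
# shared by intertwined rings are counted once.
ring_segments <- function(n, rings) {
  if (!length(rings))
    return(c(n_terminal = n))
  spans <- t(vapply(rings, function(r) c(r$donor, r$acceptor), integer(2)))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  comp <- list(spans[1, ])
  for (i in seq_len(nrow(spans))[-1]) {
    last <- comp[[length(comp)]]
    if (spans[i, 1] <= last[2]) comp[[length(comp)]] <- c(last[1], max(last[2], spans[i, 2]))
    else comp[[length(comp) + 1L]] <- spans[i, ]
  }
  segs <- c(n_terminal = comp[[1]][1] - 1L)
  for (i in seq_along(comp)) {
    segs <- c(segs, setNames(comp[[i]][2] - comp[[i]][1] + 1L,
                             paste0("ring_system_", i)))
    if (i < length(comp))
      segs <- c(segs, setNames(comp[[i + 1]][1] - comp[[i]][2] - 1L,
                               paste0("hinge_", i)))
  }
  c(segs, c_terminal = n - comp[[length(comp)]][2])
}

#' Mass of a mature peptide
#'
#' Sum of residue compositions plus one water for the termini, using IUPAC
#' average atomic weights or principal-isotope masses.
#'
#' @param mature a `mature_peptide` from [apply_maturation()].
#' @param mode `"average"` or `"monoisotopic"`.
#' @return mass in Da.
#' @export
peptide_mass <- function(mature, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  w <- ATOMIC_WEIGHT[[mode]]
  total <- colSums(mature$composition) + mature$extra + WATER
  sum(total * w[names(total)])
}

#' Plain (unmodified) peptide mass from sequence
#'
#' @param seq amino-acid string.
#' @param mode `"average"` or `"monoisotopic"`.
#' @return mass in Da.
#' @export
sequence_mass <- function(seq, mode = c("average", "monoisotopic")) {
  peptide_mass(apply_maturation(seq, modification_set()), match.arg(mode))
}
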