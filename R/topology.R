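# Stoichiometric topology of the mitochondrial engine in exact rational
# arithmetic: conservation laws (left null space of S), emergent cycles
# (right null space of the internal-species block S^X), effective reactions
# and the potential/force split of the exchanged species.
#
# Rationals are represented as parallel integer numerator/denominator
# arrays. All entries and every intermediate of Gauss-Jordan elimination on
# these tiny matrices stay far below integer overflow.

.gcd <- function(a, b) { a <- abs(a); b <- abs(b)
  while (b) { t <- b; b <- a %% b; a <- t }; a }

rat <- function(num, den = rep(1, length(num))) {
  stopifnot(all(den != 0))
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- mapply(.gcd, num, den); g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

.rat_mat <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  list(num = num, den = den)
}

.r_add <- function(a, b) rat(a$num * b$den + b$num * a$den, a$den * b$den)
.r_mul <- function(a, b) rat(a$num * b$num, a$den * b$den)
.r_neg <- function(a) list(num = -a$num, den = a$den)

# Gauss-Jordan RREF of a rational matrix; returns rref, pivot columns
.rref <- function(M) {
  num <- M$num; den <- M$den
  n <- nrow(num); m <- ncol(num)
  piv <- integer(0)
  r <- 1L
  for (cc in seq_len(m)) {
    if (r > n) break
    sel <- which(num[r:n, cc] != 0)
    if (!length(sel)) next
    i <- r + sel[1] - 1L
    if (i != r) {
      num[c(r, i), ] <- num[c(i, r), ]; den[c(r, i), ] <- den[c(i, r), ]
    }
    # scale row r so pivot = 1
    pn <- num[r, cc]; pd <- den[r, cc]
    rr <- rat(num[r, ] * pd, den[r, ] * pn)
    num[r, ] <- rr$num; den[r, ] <- rr$den
    for (k in seq_len(n)) {
      if (k == r || num[k, cc] == 0) next
      f <- list(num = num[k, cc], den = den[k, cc])
      sub <- rat(num[r, ] * f$num, den[r, ] * f$den)
      upd <- rat(num[k, ] * sub$den - sub$num * den[k, ],
                 den[k, ] * sub$den)
      num[k, ] <- upd$num; den[k, ] <- upd$den
    }
    piv <- c(piv, cc)
    r <- r + 1L
  }
  list(num = num, den = den, pivots = piv, rank = length(piv))
}

# rational null space (right) of M; columns of the result span ker(M)
.null_space <- function(M) {
  rr <- .rref(M)
  m <- ncol(M$num)
  free <- setdiff(seq_len(m), rr$pivots)
  if (!length(free)) {
    return(.rat_mat(matrix(0, m, 0), matrix(1, m, 0)))
  }
  num <- matrix(0, m, length(free)); den <- matrix(1, m, length(free))
  for (j in seq_along(free)) {
    fc <- free[j]
    num[fc, j] <- 1
    for (i in seq_along(rr$pivots)) {
      num[rr$pivots[i], j] <- -rr$num[i, fc]
      den[rr$pivots[i], j] <- rr$den[i, fc]
    }
  }
  .rat_mat(num, den)
}

.rat_to_num <- function(M) M$num / M$den

# solve A x = b over the rationals (A square, invertible)
.rat_solve <- function(A, B) {
  n <- nrow(A$num)
  aug <- .rat_mat(cbind(A$num, B$num), cbind(A$den, B$den))
  rr <- .rref(aug)
  if (!identical(rr$pivots, seq_len(n))) stop("singular rational system")
  .rat_mat(rr$num[, -(1:n), drop = FALSE], rr$den[, -(1:n), drop = FALSE])
}

#' Species and reaction catalogue of the engine
#'
#' @return list with `internal` (the 12 species appearing only in internal
#'   reactions), `exchanged` (the 12 species also touched by external
#'   processes or buffered), and `reactions` (the 11 internal reactions).
#' @export
engine_species <- function() {
  list(
    internal = c("ATPm", "ADPm", "NADH", "NAD", "OAA", "CIT", "ISOC",
                 "aKG", "SCoA", "SUC", "FUM", "MAL"),
    exchanged = c("ATPc", "ADPc", "Pim", "Hc", "Hm", "O2", "H2Om",
                  "AcCoA", "CoA", "CO2", "CoQ", "CoQH2"),
    reactions = internal_reactions()
  )
}

#' Build the stoichiometric model
#'
#' The 24 x 11 stoichiometric matrix of the 11 internal reactions over the
#' 12 internal + 12 exchanged species, with exact rational entries (the
#' oxygen coefficient of respiration is -1/2). Signs follow the
#' left-to-right direction of each chemical equation.
#'
#' @return a `stoichiometric_model`: list with `species`, `reactions`,
#'   `S` (numeric copy), `S_rat` (exact), and the `X`/`Y` row index sets.
#' @export
build_stoichiometric_model <- function() {
  sp <- engine_species()
  all_sp <- c(sp$internal, sp$exchanged)
  S2 <- matrix(0L, 24, 11, dimnames = list(all_sp, sp$reactions))
  put <- function(rxn, ...) {
    v <- c(...)
    S2[names(v), rxn] <<- S2[names(v), rxn] + as.integer(v * 2)
  }
  put("ANT", ATPm = -1, ADPc = -1, ATPc = 1, ADPm = 1)
  put("F1", ADPm = -1, Pim = -1, Hc = -3, ATPm = 1, H2Om = 1, Hm = 3)
  put("Ox", NADH = -1, Hm = -10, O2 = -0.5, NAD = 1, Hc = 10, H2Om = 1)
  put("CS", OAA = -1, AcCoA = -1, H2Om = -1, CIT = 1, CoA = 1)
  put("ACO", CIT = -1, ISOC = 1)
  put("IDH", ISOC = -1, NAD = -1, aKG = 1, NADH = 1, CO2 = 1)
  put("KGDH", aKG = -1, NAD = -1, CoA = -1, SCoA = 1, NADH = 1, CO2 = 1)
  put("SL", SCoA = -1, ADPm = -1, Pim = -1, SUC = 1, ATPm = 1, CoA = 1)
  put("SDH", SUC = -1, CoQ = -1, FUM = 1, CoQH2 = 1)
  put("FH", FUM = -1, H2Om = -1, MAL = 1)
  put("MDH", MAL = -1, NAD = -1, OAA = 1, NADH = 1)
  S_rat <- .rat_mat(S2, matrix(2, 24, 11))
  S_rat <- rat(S_rat$num, S_rat$den)
  S_rat <- list(num = matrix(S_rat$num, 24, 11, dimnames = dimnames(S2)),
                den = matrix(S_rat$den, 24, 11, dimnames = dimnames(S2)))
  out <- list(
    species = all_sp, internal = sp$internal, exchanged = sp$exchanged,
    reactions = sp$reactions,
    S = S_rat$num / S_rat$den, S_rat = S_rat,
    X_rows = seq_len(12), Y_rows = 13:24
  )
  class(out) <- "stoichiometric_model"
  out
}

.rat_submat <- function(M, rows = NULL, cols = NULL) {
  num <- M$num; den <- M$den
  if (!is.null(rows)) { num <- num[rows, , drop = FALSE]; den <- den[rows, , drop = FALSE] }
  if (!is.null(cols)) { num <- num[, cols, drop = FALSE]; den <- den[, cols, drop = FALSE] }
  list(num = num, den = den)
}

.rat_t <- function(M) list(num = t(M$num), den = t(M$den))

#' Conservation laws of the engine
#'
#' Exact left null space of S. Laws supported only on internal species are
#' unbroken (their pool totals stay conserved in the open system); the
#' remainder are broken by the exchange currents. The basis is arranged so
#' the unbroken laws (the mitochondrial adenine, pyridine and TCA pools)
#' come last.
#'
#' @param sm a `stoichiometric_model`
#' @return list with `L` (numeric 13 x 24), `L_rat`, `n_laws`, `unbroken`
#'   (row indices of the unbroken laws), `broken` (indices).
#' @export
conservation_laws <- function(sm = build_stoichiometric_model()) {
  # left null of S = right null of t(S)
  ker <- .null_space(.rat_t(sm$S_rat))
  L_rat <- .rat_t(ker)                      # rows are laws
  # unbroken laws: left null of S^X, padded with zeros on Y
  SX <- .rat_submat(sm$S_rat, rows = sm$X_rows)
  kx <- .null_space(.rat_t(SX))
  UX <- .rat_t(kx)
  nu <- nrow(UX$num)
  U_num <- cbind(UX$num, matrix(0, nu, 12))
  U_den <- cbind(UX$den, matrix(1, nu, 12))
  # broken representatives: rows of L independent modulo the unbroken ones,
  # i.e. rows whose Y-parts extend a basis of the Y-projection
  LY <- .rat_submat(L_rat, cols = 13:24)
  pick <- integer(0)
  cur <- .rat_mat(matrix(0, 0, 12), matrix(1, 0, 12))
  for (i in seq_len(nrow(L_rat$num))) {
    cand <- .rat_mat(rbind(cur$num, LY$num[i, ]), rbind(cur$den, LY$den[i, ]))
    if (.rref(cand)$rank > nrow(cur$num)) { pick <- c(pick, i); cur <- cand }
  }
  B_num <- L_rat$num[pick, , drop = FALSE]
  B_den <- L_rat$den[pick, , drop = FALSE]
  L_num <- rbind(B_num, U_num); L_den <- rbind(B_den, U_den)
  nb <- length(pick)
  lab <- c(sprintf("broken_%d", seq_len(nb)), sprintf("unbroken_%d", seq_len(nu)))
  dimnames(L_num) <- list(lab, sm$species); dimnames(L_den) <- dimnames(L_num)
  list(L = L_num / L_den, L_rat = list(num = L_num, den = L_den),
       n_laws = nb + nu, unbroken = nb + seq_len(nu), broken = seq_len(nb))
}

#' Emergent cycles and effective reactions
#'
#' Exact right null space of the internal-species block S^X, rotated to the
#' canonical generators: the first cycle produces one cytosolic ATP and no
#' net cytosolic proton (`r1`), the second translocates one proton and no
#' ATP (`r2`). Their images under S^Y are the effective reactions.
#'
#' @param sm a `stoichiometric_model`
#' @param force_species two exchanged species used to normalize the basis
#'   (each generator produces exactly one unit of "its" force species and
#'   none of the other)
#' @return list with `C` (11 x 2 numeric, columns `r1`, `r2`), `C_rat`,
#'   `n_cycles`, and `effective` — a tibble of the exact effective
#'   stoichiometries (columns `species`, `r1`, `r2`, and rational
#'   num/den pairs).
#' @export
emergent_cycles <- function(sm = build_stoichiometric_model(),
                            force_species = c("ATPc", "Hc")) {
  SX <- .rat_submat(sm$S_rat, rows = sm$X_rows)
  ker <- .null_space(SX)                    # 11 x k
  k <- ncol(ker$num)
  SY <- .rat_submat(sm$S_rat, rows = sm$Y_rows)
  # rows of S^Y c for the force species over the raw basis
  ia <- match(force_species, sm$exchanged)
  if (anyNA(ia)) stop("force_species must be exchanged species", call. = FALSE)
  M_num <- matrix(0, 2, k); M_den <- matrix(1, 2, k)
  for (j in seq_len(k)) {
    for (r in 1:2) {
      acc <- list(num = 0, den = 1)
      for (q in seq_len(11)) {
        acc <- .r_add(acc, .r_mul(
          list(num = SY$num[ia[r], q], den = SY$den[ia[r], q]),
          list(num = ker$num[q, j], den = ker$den[q, j])))
      }
      M_num[r, j] <- acc$num; M_den[r, j] <- acc$den
    }
  }
  # rotate: find W with M W = I2  (k = 2 for this network)
  W <- .rat_solve(.rat_mat(M_num, M_den), .rat_mat(diag(2), matrix(1, 2, 2)))
  C_num <- matrix(0, 11, 2); C_den <- matrix(1, 11, 2)
  for (j in 1:2) for (q in seq_len(11)) {
    acc <- list(num = 0, den = 1)
    for (l in seq_len(k)) {
      acc <- .r_add(acc, .r_mul(
        list(num = ker$num[q, l], den = ker$den[q, l]),
        list(num = W$num[l, j], den = W$den[l, j])))
    }
    C_num[q, j] <- acc$num; C_den[q, j] <- acc$den
  }
  dimnames(C_num) <- list(sm$reactions, c("r1", "r2"))
  dimnames(C_den) <- dimnames(C_num)
  # effective reactions S^Y c
  E_num <- matrix(0, 12, 2); E_den <- matrix(1, 12, 2)
  for (j in 1:2) for (r in seq_len(12)) {
    acc <- list(num = 0, den = 1)
    for (q in seq_len(11)) {
      acc <- .r_add(acc, .r_mul(
        list(num = SY$num[r, q], den = SY$den[r, q]),
        list(num = C_num[q, j], den = C_den[q, j])))
    }
    E_num[r, j] <- acc$num; E_den[r, j] <- acc$den
  }
  eff <- tibble::tibble(
    species = sm$exchanged,
    r1 = E_num[, 1] / E_den[, 1], r2 = E_num[, 2] / E_den[, 2],
    r1_num = E_num[, 1], r1_den = E_den[, 1],
    r2_num = E_num[, 2], r2_den = E_den[, 2]
  )
  list(C = C_num / C_den, C_rat = list(num = C_num, den = C_den),
       n_cycles = k, effective = eff)
}

#' Potential/force split of the exchanged species
#'
#' Verifies that the broken-conservation-law submatrix over a candidate set
#' of potential species is invertible and returns the relabeled broken-law
#' basis `(L^b_Yp)^{-1} L^b`, in which each broken law is tied to exactly
#' one potential species. The remaining exchanged species are the force
#' species carrying the nonconservative forces.
#'
#' @param laws result of [conservation_laws()]
#' @param sm the `stoichiometric_model`
#' @param Yp character vector of candidate potential species (default: the
#'   model's canonical choice, leaving `ATPc` and `Hc` as force species)
#' @return list with `Yp`, `Yf`, `invertible`, and `L_relabeled`
#'   (numeric matrix, rows labeled by potential species). Errors with an
#'   explicit report when the submatrix is singular.
#' @export
potential_force_split <- function(laws = conservation_laws(),
                                  sm = build_stoichiometric_model(),
                                  Yp = c("ADPc", "Pim", "Hm", "O2", "H2Om",
                                         "AcCoA", "CoA", "CO2", "CoQ",
                                         "CoQH2")) {
  stopifnot(all(Yp %in% sm$exchanged))
  Yf <- setdiff(sm$exchanged, Yp)
  bi <- laws$broken
  cols <- match(Yp, sm$species)
  A <- .rat_submat(laws$L_rat, rows = bi, cols = cols)
  if (nrow(A$num) != ncol(A$num)) {
    stop(sprintf("broken-law submatrix is %d x %d, not square",
                 nrow(A$num), ncol(A$num)), call. = FALSE)
  }
  inv <- tryCatch(
    .rat_solve(A, .rat_mat(diag(nrow(A$num)),
                           matrix(1, nrow(A$num), nrow(A$num)))),
    error = function(e) NULL)
  if (is.null(inv)) {
    stop("L^b_Yp is singular for Yp = {", paste(Yp, collapse = ", "),
         "}: not a valid potential/force split", call. = FALSE)
  }
  Lb <- .rat_submat(laws$L_rat, rows = bi)
  n <- length(bi)
  R_num <- matrix(0, n, 24); R_den <- matrix(1, n, 24)
  for (i in seq_len(n)) for (j in seq_len(24)) {
    acc <- list(num = 0, den = 1)
    for (l in seq_len(n)) {
      acc <- .r_add(acc, .r_mul(
        list(num = inv$num[i, l], den = inv$den[i, l]),
        list(num = Lb$num[l, j], den = Lb$den[l, j])))
    }
    R_num[i, j] <- acc$num; R_den[i, j] <- acc$den
  }
  dimnames(R_num) <- list(Yp, sm$species); dimnames(R_den) <- dimnames(R_num)
  list(Yp = Yp, Yf = Yf, invertible = TRUE, L_relabeled = R_num / R_den)
}

# pretty-print a rational as "a/b"
.frac_chr <- function(num, den) {
  ifelse(num == 0, "0", ifelse(den == 1, as.character(num),
                               paste0(num, "/", den)))
}

#' Topology report
#'
#' Human-readable and machine-readable summary: dimensions of the law and
#' cycle spaces, the unbroken pools, the cycle generators and the effective
#' reactions with exact fractions.
#'
#' @param path optional file path; when given, the machine-readable twin is
#'   written there as JSON
#' @return (invisibly) the report list.
#' @export
topology_report <- function(path = NULL) {
  sm <- build_stoichiometric_model()
  laws <- conservation_laws(sm)
  cyc <- emergent_cycles(sm)
  split <- potential_force_split(laws, sm)
  rep <- list(
    n_species = length(sm$species), n_internal_reactions = length(sm$reactions),
    n_conservation_laws = laws$n_laws, n_unbroken = length(laws$unbroken),
    n_emergent_cycles = cyc$n_cycles,
    unbroken_pools = lapply(laws$unbroken, function(i) {
      v <- laws$L[i, ]
      as.list(v[v != 0])
    }),
    cycles = list(r1 = as.list(stats::setNames(cyc$C[, 1], sm$reactions)),
                  r2 = as.list(stats::setNames(cyc$C[, 2], sm$reactions))),
    effective_reactions = list(
      r1 = as.list(stats::setNames(
        .frac_chr(cyc$effective$r1_num, cyc$effective$r1_den),
        cyc$effective$species)),
      r2 = as.list(stats::setNames(
        .frac_chr(cyc$effective$r2_num, cyc$effective$r2_den),
        cyc$effective$species))),
    potential_species = split$Yp, force_species = split$Yf
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(rep)
}

#' Export the stoichiometric matrix as TSV
#'
#' Writes species-by-reaction stoichiometry with exact fractional entries
#' rendered as strings (plus a reaction list with reversibility flags) for
#' interoperability.
#'
#' @param path output TSV path
#' @param sm the `stoichiometric_model`
#' @return invisibly `path`.
#' @export
export_stoichiometry_tsv <- function(path, sm = build_stoichiometric_model()) {
  M <- matrix(.frac_chr(sm$S_rat$num, sm$S_rat$den), nrow = 24,
              dimnames = dimnames(sm$S_rat$num))
  df <- data.frame(species = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
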