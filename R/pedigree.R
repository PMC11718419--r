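#' Pedigree with founder priors
#'
#' Directed parent links plus optional founder baseline inbreeding and
#' declared kinships between founder pairs.  Founders have both parents
#' `NA`; every non-founder must have both parents present in the pedigree
#' (no half-known parentage), and the graph must be acyclic.
#'
#' @param id integer/character vector of unique individual ids.
#' @param sire,dam parent ids (`NA` for founders; both or neither).
#' @param founder_f named numeric vector of baseline inbreeding
#'   coefficients for founders (default 0 for all founders).
#' @param founder_kinship optional data.frame `id1, id2, k` declaring known
#'   kinship coefficients between founder pairs (e.g. 0.25 for a
#'   mother-son or full-sib founder pair); undeclared pairs are unrelated.
#' @return object of class `pedigree`.
#' @examples
#' # offspring of a full-sib mating
#' p <- pedigree(id = c("a", "b", "s1", "s2", "x"),
#'               sire = c(NA, NA, "a", "a", "s1"),
#'               dam  = c(NA, NA, "b", "b", "s2"))
#' inbreeding_coefficient(p, "x")  # 0.25
#' @export
pedigree <- function(id, sire, dam, founder_f = NULL, founder_kinship = NULL) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  if (any(xor(is.na(sire), is.na(dam)))) {
    stop("individuals must have both parents known or be founders (both NA)")
  }
  known <- c(sire, dam); known <- known[!is.na(known)]
  if (!all(known %in% id)) {
    stop("unknown parent id(s): ",
         paste(unique(setdiff(known, id)), collapse = ", "))
  }
  is_founder <- is.na(sire)
  f <- stats::setNames(rep(0, sum(is_founder)), id[is_founder])
  if (!is.null(founder_f)) {
    bad <- setdiff(names(founder_f), names(f))
    if (length(bad)) stop("founder_f given for non-founders: ",
                          paste(bad, collapse = ", "))
    if (any(founder_f < 0 | founder_f > 1)) stop("founder_f outside [0,1]")
    f[names(founder_f)] <- founder_f
  }
  if (!is.null(founder_kinship)) {
    stopifnot(all(c("id1", "id2", "k") %in% names(founder_kinship)))
    fk <- founder_kinship
    if (!all(c(fk$id1, fk$id2) %in% names(f))) {
      stop("founder_kinship may only reference founders")
    }
    if (any(fk$k < 0 | fk$k > 0.5)) stop("founder kinships outside [0, 0.5]")
  }
  ord <- pedigree_toposort(id, sire, dam)
  structure(list(id = id, sire = sire, dam = dam, founder_f = f,
                 founder_kinship = founder_kinship, order = ord),
            class = "pedigree")
}

## Kahn topological sort; errors on cycles (an individual its own ancestor)
pedigree_toposort <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L); out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) stop("pedigree contains a cycle")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", length(x$id), "members,", sum(is.na(x$sire)),
      "founders\n")
  if (any(x$founder_f > 0)) {
    cat("founder baseline F > 0 for",
        sum(x$founder_f > 0), "founder(s)\n")
  }
  if (!is.null(x$founder_kinship)) {
    cat(nrow(x$founder_kinship), "declared founder kinship pair(s)\n")
  }
  invisible(x)
}

#' Full kinship matrix of a pedigree
#'
#' Emik-Terrill tabular recursion in topological order:
#' `f(i, j) = (f(sire_i, j) + f(dam_i, j)) / 2` for a non-founder `i` not
#' an ancestor of `j`, and `f(i, i) = (1 + F_i) / 2` with
#' `F_i = f(sire_i, dam_i)`.  Founder self-kinship is `(1 + founder_f) / 2`
#' and declared founder-pair kinships seed the off-diagonals.
#'
#' @param ped pedigree.
#' @return symmetric numeric matrix with ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  fidx <- which(is.na(si))
  diag(K)[fidx] <- (1 + ped$founder_f[ped$id[fidx]]) / 2
  if (!is.null(ped$founder_kinship)) {
    i1 <- match(as.character(ped$founder_kinship$id1), ped$id)
    i2 <- match(as.character(ped$founder_kinship$id2), ped$id)
    K[cbind(i1, i2)] <- ped$founder_kinship$k
    K[cbind(i2, i1)] <- ped$founder_kinship$k
  }
  for (i in ped$order) {
    if (is.na(si[i])) next
    prev <- ped$order[seq_len(match(i, ped$order) - 1L)]
    K[i, prev] <- (K[si[i], prev] + K[di[i], prev]) / 2
    K[prev, i] <- K[i, prev]
    K[i, i] <- (1 + K[si[i], di[i]]) / 2
  }
  K
}

#' Pairwise kinship coefficient
#'
#' @param ped pedigree.
#' @param i,j individual ids.
#' @return kinship coefficient in `[0, 1]`.
#' @export
kinship <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  i <- as.character(i); j <- as.character(j)
  bad <- setdiff(c(i, j), ped$id)
  if (length(bad)) stop("unknown id(s): ", paste(bad, collapse = ", "))
  K <- kinship_matrix(ped)
  K[cbind(i, j)]
}

#' Pedigree inbreeding coefficient (identity by descent)
#'
#' `F_i` is the kinship of the parents; founders return their baseline
#' `founder_f`.
#'
#' @param ped pedigree.
#' @param i individual id(s); default all members.
#' @return named numeric vector of F values.
#' @export
inbreeding_coefficient <- function(ped, i = ped$id) {
  stopifnot(inherits(ped, "pedigree"))
  i <- as.character(i)
  bad <- setdiff(i, ped$id)
  if (length(bad)) stop("unknown id(s): ", paste(bad, collapse = ", "))
  K <- kinship_matrix(ped)
  Fv <- 2 * diag(K) - 1
  stats::setNames(Fv[match(i, ped$id)], i)
}

#' Read / write pedigrees
#'
#' Three-column CSV (`id, sire, dam`; empty or `0` = founder) with an
#' optional sidecar CSV of founder attributes (`id, founder_f`).
#'
#' @param path pedigree CSV.
#' @param founder_path optional founder-attribute CSV.
#' @return pedigree.
#' @export
read_pedigree <- function(path, founder_path = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  stopifnot(all(c("id", "sire", "dam") %in% names(d)))
  d$sire[d$sire %in% c("", "0", "NA")] <- NA
  d$dam[d$dam %in% c("", "0", "NA")] <- NA
  founder_f <- NULL
  if (!is.null(founder_path)) {
    fa <- utils::read.csv(founder_path, stringsAsFactors = FALSE)
    founder_f <- stats::setNames(as.numeric(fa$founder_f),
                                 as.character(fa$id))
  }
  pedigree(d$id, d$sire, d$dam, founder_f = founder_f)
}

#' @rdname read_pedigree
#' @param ped pedigree object.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  d <- data.frame(id = ped$id,
                  sire = ifelse(is.na(ped$sire), "0", ped$sire),
                  dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
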