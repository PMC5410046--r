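#' Build and validate a pedigree
#'
#' Normalizes unknown parents (empty string or NA) to `NA`, checks id
#' uniqueness and parent presence, and topologically sorts the records so
#' that every parent precedes its offspring. Individuals with a parental
#' cycle (including self-parentage) raise an error.
#'
#' @param records data frame with columns `id`, `sire`, `dam` and optionally
#'   `family`, `provenance`.
#' @return data frame of class `pedigree`, topologically sorted.
#' @export
build_pedigree <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sire", "dam") %in% names(records)))
  ped <- records
  for (col in c("id", "sire", "dam"))
    ped[[col]] <- as.character(ped[[col]])
  for (col in c("sire", "dam"))
    ped[[col]][!is.na(ped[[col]]) & ped[[col]] == ""] <- NA_character_
  if (!"family" %in% names(ped)) ped$family <- NA_character_
  if (!"provenance" %in% names(ped)) ped$provenance <- NA_character_
  if (anyDuplicated(ped$id))
    stop("duplicate individual ids in pedigree", call. = FALSE)
  known <- ped$id
  refs <- stats::na.omit(c(ped$sire, ped$dam))
  miss <- setdiff(refs, known)
  if (length(miss))
    stop("referenced parents absent from pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)

  # Kahn topological sort on the parent -> offspring DAG
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  # stable variant: among available records always take the earliest input
  # position, so sorting preserves the original order within generations
  avail <- indeg == 0
  done <- rep(FALSE, n)
  ord <- integer(0)
  while (any(avail)) {
    v <- which(avail)[1]
    avail[v] <- FALSE; done[v] <- TRUE
    ord <- c(ord, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0 && !done[w]) avail[w] <- TRUE
    }
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle (an individual is its own ancestor)",
         call. = FALSE)
  out <- ped[ord, c("id", "sire", "dam", "family", "provenance")]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Numerator relationship matrix (tabular method)
#'
#' Computes the additive (numerator) relationship matrix A from a sorted
#' pedigree by the recursive tabular method:
#' `A[i,i] = 1 + 0.5 * A[sire, dam]` and
#' `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])` for `j` prior to `i`, with
#' absent parents contributing zero. Founders are assumed unrelated and
#' non-inbred.
#'
#' @param pedigree a [build_pedigree()] result (or raw records, which are
#'   built first).
#' @return dense symmetric matrix with individual ids as dimnames.
#' @export
numerator_relationship_matrix <- function(pedigree) {
  if (!inherits(pedigree, "pedigree")) pedigree <- build_pedigree(pedigree)
  n <- nrow(pedigree)
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  if (any(!is.na(si) & si >= seq_len(n)) ||
      any(!is.na(di) & di >= seq_len(n)))
    stop("pedigree not sorted: parent appears after offspring", call. = FALSE)
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      prev <- seq_len(i - 1)
      as <- if (!is.na(s)) A[prev, s] else 0
      ad <- if (!is.na(d)) A[prev, d] else 0
      v <- 0.5 * (as + ad)
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

# Inverse of A with a small diagonal jitter if numerically singular.
.ainverse <- function(A, jitter = 1e-8) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out))
    out <- solve(A + diag(jitter, nrow(A)))
  dimnames(out) <- dimnames(A)
  out
}

#' Classify pairs of individuals by pedigree relatedness
#'
#' Classifies pairs using declared parent ids: `full_sib` = same sire and
#' dam, `half_sib` = exactly one shared parent, `parent_offspring` = one is
#' a parent of the other, `self` = identical ids. `unrelated` additionally
#' requires a zero additive relationship, to guard against relatedness
#' through deeper pedigree links; remaining pairs are `other_related`.
#'
#' @param pedigree a [build_pedigree()] result.
#' @param ids optional subset of ids (default: all); pairs are all unordered
#'   pairs within the subset.
#' @param A optional precomputed relationship matrix (computed if missing
#'   and needed).
#' @return data frame with columns `id1`, `id2`, `class`.
#' @export
classify_pairs <- function(pedigree, ids = NULL, A = NULL) {
  if (!inherits(pedigree, "pedigree")) pedigree <- build_pedigree(pedigree)
  if (is.null(ids)) ids <- pedigree$id
  idx <- match(ids, pedigree$id)
  if (anyNA(idx)) stop("unknown ids", call. = FALSE)
  if (is.null(A)) A <- numerator_relationship_matrix(pedigree)
  pr <- utils::combn(length(ids), 2)
  i1 <- ids[pr[1, ]]; i2 <- ids[pr[2, ]]
  s1 <- pedigree$sire[match(i1, pedigree$id)]
  d1 <- pedigree$dam[match(i1, pedigree$id)]
  s2 <- pedigree$sire[match(i2, pedigree$id)]
  d2 <- pedigree$dam[match(i2, pedigree$id)]
  # shared parents as a set intersection: in a diallel the same parent can
  # serve as sire in one cross and dam in another
  shared <- mapply(function(a, b, x, y)
    length(intersect(stats::na.omit(c(a, b)), stats::na.omit(c(x, y)))),
    s1, d1, s2, d2, USE.NAMES = FALSE)
  po <- (i1 == ifelse(is.na(s2), "", s2)) | (i1 == ifelse(is.na(d2), "", d2)) |
    (i2 == ifelse(is.na(s1), "", s1)) | (i2 == ifelse(is.na(d1), "", d1))
  aval <- A[cbind(match(i1, rownames(A)), match(i2, colnames(A)))]
  cls <- ifelse(po, "parent_offspring",
         ifelse(shared == 2, "full_sib",
         ifelse(shared == 1, "half_sib",
         ifelse(aval == 0, "unrelated", "other_related"))))
  data.frame(id1 = i1, id2 = i2, class = cls, stringsAsFactors = FALSE)
}

#' Gene-dropping estimate of additive relationships
#'
#' Monte-Carlo oracle for the tabular method: founders receive unique
#' allele labels, alleles are dropped through the pedigree by Mendelian
#' sampling, and expected allele sharing is accumulated over replicates.
#' `A[i,j] = 2 * kinship(i,j)` where kinship is the probability that random
#' alleles drawn from i and j are identical by descent; the diagonal is
#' `1 + F_i` with `F_i` the probability the two alleles of i are IBD.
#'
#' @param pedigree a [build_pedigree()] result.
#' @param n_rep number of gene-dropping replicates.
#' @param seed optional integer seed.
#' @return estimated relationship matrix.
#' @export
gene_drop_relationship <- function(pedigree, n_rep = 100000, seed = NULL) {
  if (!inherits(pedigree, "pedigree")) pedigree <- build_pedigree(pedigree)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pedigree)
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  # allele labels per individual, replicated columns = replicates
  a1 <- matrix(0L, n, n_rep)
  a2 <- matrix(0L, n, n_rep)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      a1[i, ] <- lab + 1L
      a2[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick1 <- stats::runif(n_rep) < 0.5
      a1[i, ] <- ifelse(pick1, a1[si[i], ], a2[si[i], ])
      pick2 <- stats::runif(n_rep) < 0.5
      a2[i, ] <- ifelse(pick2, a1[di[i], ], a2[di[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + mean(a1[i, ] == a2[i, ])
    if (i < n) for (j in seq((i + 1), n)) {
      kin <- (colSums(rbind(a1[i, ] == a1[j, ], a1[i, ] == a2[j, ],
                            a2[i, ] == a1[j, ], a2[i, ] == a2[j, ]))) / 4
      A[i, j] <- A[j, i] <- 2 * mean(kin)
    }
  }
  A
}

#' Read / write pedigree CSV
#'
#' Columns `id,sire,dam,family,provenance`; empty fields mean unknown.
#' @param path file path.
#' @name pedigree_io
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("", "NA"))
  build_pedigree(df)
}

#' @rdname pedigree_io
#' @param pedigree pedigree to write.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- as.data.frame(pedigree)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a relationship matrix as TSV with id header row/column
#' @param A relationship matrix with dimnames.
#' @param path file path.
#' @export
write_relationship_matrix <- function(A, path) {
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
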