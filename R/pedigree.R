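## Pedigree construction, validation and kinship computation.

.normalizeSex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  if (anyNA(out))
    stop("unrecognised sex codes: ",
         paste(unique(s[is.na(out)]), collapse = ", "),
         " (accepted: 1/2, m/f, male/female)")
  out
}

.normalizeParent <- function(p) {
  p <- trimws(as.character(p))
  p[p %in% c("", "0", "NA")] <- NA_character_
  p
}

# Kahn topological sort over the parent relation; detects cycles and
# reports the members involved.
.topoOrder <- function(id, fatherIdx, motherIdx) {
  n <- length(id)
  nChild <- integer(n)          # out-edges parent -> child
  childOf <- vector("list", n)
  indeg <- integer(n)
  for (k in seq_len(n)) {
    for (p in c(fatherIdx[k], motherIdx[k])) {
      if (!is.na(p)) {
        childOf[[p]] <- c(childOf[[p]], k)
        indeg[k] <- indeg[k] + 1L
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in childOf[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n)
    stop("cycle detected in pedigree involving: ",
         paste(id[setdiff(seq_len(n), order)], collapse = ", "))
  order
}

#' Load and validate a pedigree
#'
#' Builds a \linkS4class{Pedigree} from a table with columns \code{id},
#' \code{father}, \code{mother}, \code{sex}. Missing parents may be coded
#' \code{NA}, empty, or \code{"0"}; sex may be coded \code{1}/\code{2},
#' \code{m}/\code{f} or \code{male}/\code{female}. Validation enforces:
#' unique ids; both parents present or both missing (half-known parentage is
#' rejected, not auto-completed, because silently adding a dummy founder
#' changes kinship values); parents exist in the table; fathers are male and
#' mothers female; and the parent relation is acyclic. Identifiers are
#' compared as exact strings.
#'
#' @param table data.frame (or coercible) with columns id, father, mother, sex.
#' @return a validated \linkS4class{Pedigree}.
#' @examples
#' trio <- data.frame(id = c("F1", "M1", "C1"), father = c(0, 0, "F1"),
#'                    mother = c(0, 0, "M1"), sex = c(1, 2, 2))
#' ped <- loadPedigree(trio)
#' sum(isFounder(ped))  # 2
#' @export
loadPedigree <- function(table) {
  table <- as.data.frame(table)
  need <- c("id", "father", "mother", "sex")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("pedigree table lacks columns: ", paste(miss, collapse = ", "))
  id <- trimws(as.character(table$id))
  if (anyDuplicated(id))
    stop("duplicate ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  father <- .normalizeParent(table$father)
  mother <- .normalizeParent(table$mother)
  sex <- .normalizeSex(table$sex)
  mixed <- xor(is.na(father), is.na(mother))
  if (any(mixed))
    stop("half-known parentage (exactly one parent missing) for: ",
         paste(id[mixed], collapse = ", "))
  fi <- match(father, id); mi <- match(mother, id)
  bad <- (!is.na(father) & is.na(fi)) | (!is.na(mother) & is.na(mi))
  if (any(bad))
    stop("unknown parent id for members: ", paste(id[bad], collapse = ", "))
  ord <- .topoOrder(id, fi, mi)
  new("Pedigree", id = id, father = father, mother = mother, sex = sex,
      topoOrder = as.integer(ord))
}

#' Read a pedigree file
#'
#' Comma- or tab-separated file with header \code{id,father,mother,sex};
#' the delimiter is auto-detected. See [loadPedigree()] for the accepted
#' missing-parent and sex encodings.
#'
#' @param path file path.
#' @return a \linkS4class{Pedigree}.
#' @export
readPedigreeFile <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  loadPedigree(as.data.frame(dt))
}

#' @export
#' @describeIn loadPedigree write a pedigree back to file (CSV, founders'
#'   parents written as \code{0}, sex as 1/2).
#' @param ped a \linkS4class{Pedigree}.
#' @param path output path.
writePedigreeFile <- function(ped, path) {
  df <- data.frame(id = ped@id,
                   father = ifelse(is.na(ped@father), "0", ped@father),
                   mother = ifelse(is.na(ped@mother), "0", ped@mother),
                   sex = ifelse(ped@sex == "male", 1L, 2L))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname memberIds
#' @export
setMethod("memberIds", "Pedigree", function(x) x@id)

#' @rdname isFounder
#' @export
setMethod("isFounder", "Pedigree",
          function(x) setNames(is.na(x@father), x@id))

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@father))
  cat("Pedigree with", length(object@id), "members (",
      nf, "founders,", length(object@id) - nf, "non-founders )\n")
  cat("  sex: ", sum(object@sex == "male"), "male /",
      sum(object@sex == "female"), "female\n")
})

# parent indices in topological order (0 = founder), used by the C++ kernels
.topoParents <- function(ped) {
  ord <- ped@topoOrder
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  fi <- match(ped@father, ped@id)[ord]
  mi <- match(ped@mother, ped@id)[ord]
  list(father = ifelse(is.na(fi), 0L, pos[fi]),
       mother = ifelse(is.na(mi), 0L, pos[mi]),
       order = ord, pos = pos)
}

#' @rdname kinship
#' @export
setMethod("kinship", "Pedigree", function(x) {
  n <- length(x@id)
  tp <- .topoParents(x)
  ph <- matrix(0, n, n)
  f <- tp$father; m <- tp$mother
  for (k in seq_len(n)) {
    if (f[k] == 0L) {
      ph[k, k] <- 0.5
    } else {
      if (k > 1L) {
        prev <- seq_len(k - 1L)
        v <- 0.5 * (ph[f[k], prev] + ph[m[k], prev])
        ph[k, prev] <- v
        ph[prev, k] <- v
      }
      ph[k, k] <- 0.5 * (1 + ph[f[k], m[k]])
    }
  }
  # back to input order
  inv <- order(tp$order)
  ph <- ph[inv, inv, drop = FALSE]
  dimnames(ph) <- list(x@id, x@id)
  new("KinshipMatrix", ids = x@id, phi = ph)
})

#' Monte-Carlo kinship by gene dropping
#'
#' Independent check of the kinship recursion: each founder receives two
#' unique allele labels, one allele per parent is transmitted at random down
#' the pedigree, and \eqn{\phi(i,j)} is estimated as the mean over drops of
#' one quarter of the number of label-identical pairs among the four
#' cross-individual allele pairs (the diagonal uses
#' \eqn{[1 + P(\mathrm{autozygous})]/2}).
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param nDrops number of independent gene drops (>= 1).
#' @param seed optional integer seed.
#' @return a \linkS4class{KinshipMatrix} of Monte-Carlo estimates.
#' @export
kinshipMC <- function(ped, nDrops, seed = NULL) {
  stopifnot(nDrops >= 1)
  if (!is.null(seed)) set.seed(seed)
  tp <- .topoParents(ped)
  ph <- cpp_kinship_mc(tp$father, tp$mother, as.integer(nDrops))
  inv <- order(tp$order)
  ph <- ph[inv, inv, drop = FALSE]
  dimnames(ph) <- list(ped@id, ped@id)
  new("KinshipMatrix", ids = ped@id, phi = ph)
}

#' @rdname phi
#' @export
setMethod("phi", "KinshipMatrix", function(x) x@phi)

#' @rdname twoPhi
#' @export
setMethod("twoPhi", "KinshipMatrix", function(x) 2 * x@phi)

#' @rdname twoPhi
#' @export
setMethod("twoPhi", "Pedigree", function(x) 2 * phi(kinship(x)))

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix over", length(object@ids), "individuals\n")
  off <- object@phi[upper.tri(object@phi)]
  if (length(off))
    cat(sprintf("  mean off-diagonal phi: %.4f (max %.4f)\n",
                mean(off), max(off)))
})
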