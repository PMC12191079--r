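#' Electrode montage with hemispheric and frontal-caudal pairings
#'
#' A montage defines the electrode space of the recording cap: the ordered
#' electrode labels, which of them sit on the midline, which left/right
#' pairs are homologous across hemispheres (driving the DASM/RASM asymmetry
#' features), and which frontal/posterior pairs are used for the
#' differential-caudality (DCAU) features.
#'
#' @param labels character vector of electrode names in recording order,
#'   following extended 10-20 naming: odd numeric suffix = left hemisphere,
#'   even = right hemisphere, trailing `z`/`Z` = midline.
#' @param caudal_pairs integer matrix with columns `frontal`, `posterior`
#'   (indices into `labels`), or `NULL` if no caudal pairing is defined.
#'
#' @return An object of class `montage`: a list with elements `labels`,
#'   `midline` (logical per label), `mirror_pairs` (n x 2 integer matrix,
#'   columns `left`, `right`), and `caudal_pairs`.
#' @seealso [load_default_montage()], [derive_mirror_pairs()]
#' @export
montage <- function(labels, caudal_pairs = NULL) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  if (anyDuplicated(labels)) {
    stop("montage labels must be unique")
  }
  midline <- is_midline_label(labels)
  mirror <- derive_mirror_pairs(labels)
  if (!is.null(caudal_pairs)) {
    caudal_pairs <- as.matrix(caudal_pairs)
    storage.mode(caudal_pairs) <- "integer"
    if (ncol(caudal_pairs) != 2L ||
        any(caudal_pairs < 1L) || any(caudal_pairs > length(labels))) {
      stop("caudal_pairs must be a two-column matrix of valid label indices")
    }
    colnames(caudal_pairs) <- c("frontal", "posterior")
  }
  structure(
    list(labels = labels, midline = midline,
         mirror_pairs = mirror, caudal_pairs = caudal_pairs),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf(
    "<montage> %d electrodes (%d midline), %d mirror pairs, %d caudal pairs\n",
    length(x$labels), sum(x$midline), nrow(x$mirror_pairs),
    if (is.null(x$caudal_pairs)) 0L else nrow(x$caudal_pairs)))
  invisible(x)
}

is_midline_label <- function(labels) {
  grepl("[zZ]$", labels)
}

#' Derive left-right homologous electrode pairs from 10-20 labels
#'
#' Pairs each left-hemisphere electrode (odd numeric suffix) with its
#' right-hemisphere homolog (same prefix, suffix + 1). Midline labels
#' (trailing `z`/`Z`) are excluded. On the packaged 62-channel cap this
#' yields the 27 pairs underlying the DASM and RASM feature families.
#'
#' @param labels character vector of electrode names.
#' @return Integer matrix with columns `left`, `right`; zero rows when no
#'   lateral electrodes are present.
#' @export
#' @examples
#' derive_mirror_pairs(c("F3", "F4", "FZ"))  # one pair: F3-F4
derive_mirror_pairs <- function(labels) {
  stopifnot(is.character(labels))
  midline <- is_midline_label(labels)
  suffix <- suppressWarnings(
    as.integer(sub("^.*?([0-9]+)$", "\\1", labels)))
  has_num <- grepl("[0-9]+$", labels)
  prefix <- sub("[0-9]+$", "", labels)
  lateral <- has_num & !midline
  if (any(!lateral & !midline)) {
    bad <- labels[!lateral & !midline]
    stop("label(s) neither midline nor numbered lateral: ",
         paste(bad, collapse = ", "))
  }
  left <- which(lateral & suffix %% 2L == 1L)
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("left", "right")))
  for (i in left) {
    target_suffix <- suffix[i] + 1L
    j <- which(prefix == prefix[i] & has_num & suffix == target_suffix)
    if (length(j) != 1L) {
      stop(sprintf("left electrode '%s' has no right homolog '%s%d'",
                   labels[i], prefix[i], target_suffix))
    }
    pairs <- rbind(pairs, c(i, j))
  }
  # right electrodes must all have been claimed by a left homolog
  right <- which(lateral & suffix %% 2L == 0L)
  unclaimed <- setdiff(right, pairs[, 2L])
  if (length(unclaimed) > 0L) {
    stop(sprintf("right electrode '%s' has no left homolog",
                 labels[unclaimed[1L]]))
  }
  colnames(pairs) <- c("left", "right")
  pairs
}

#' Load the packaged 62-channel montage
#'
#' Reads the `esi62` resource shipped with the package: the 62 extended
#' 10-20 labels of the standard 62-channel research cap, from which 27
#' left-right mirror pairs are derived programmatically and 23
#' frontal-posterior pairs are read from the resource table. The caudal
#' pairing cannot be derived from label names alone and follows the common
#' convention for this cap in the affective-EEG literature; the CSV is
#' user-editable for other conventions.
#'
#' @param path path to a montage CSV with columns `label`, `midline`,
#'   `mirror_of`, `caudal_partner`; defaults to the packaged `esi62` file.
#' @return A [montage()] with 62 labels, 27 mirror pairs, 23 caudal pairs.
#' @export
load_default_montage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "esi62.csv", package = "eegatt",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "logical",
                                        "character", "character"))
  required <- c("label", "midline", "mirror_of", "caudal_partner")
  if (!all(required %in% names(tab)) || anyNA(tab$midline)) {
    stop("corrupted montage resource: expected columns ",
         paste(required, collapse = ", "))
  }
  labels <- tab$label
  frontal <- which(!is.na(tab$caudal_partner) & nzchar(tab$caudal_partner))
  posterior <- match(tab$caudal_partner[frontal], labels)
  if (anyNA(posterior)) {
    stop("corrupted montage resource: caudal_partner '",
         tab$caudal_partner[frontal][which(is.na(posterior))[1L]],
         "' is not a montage label")
  }
  m <- montage(labels, caudal_pairs = cbind(frontal, posterior))
  # cross-check declared midline flags and mirror assignments
  if (!identical(m$midline, tab$midline)) {
    stop("corrupted montage resource: midline flags disagree with labels")
  }
  declared <- which(nzchar(tab$mirror_of))
  for (i in declared) {
    j <- match(tab$mirror_of[i], labels)
    row <- m$mirror_pairs[m$mirror_pairs[, "left"] == i, , drop = FALSE]
    if (is.na(j) || nrow(row) != 1L || row[1L, "right"] != j) {
      stop("corrupted montage resource: mirror_of for '", labels[i],
           "' disagrees with derived pairing")
    }
  }
  m
}
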