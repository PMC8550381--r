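#' Discretize a continuous trait by gap coding
#'
#' Places the `k - 1` class boundaries in the `k - 1` widest gaps between
#' consecutive distinct sorted values, so classes are separated by the largest
#' breaks in the empirical distribution. This is the conventional way to bin,
#' e.g., maximum body lengths into small/medium/large categories. Ties in gap
#' width are broken toward the smaller values, and each breakpoint is reported
#' as the midpoint of its gap.
#'
#' @param values Numeric vector (e.g. total length in cm); `NA` allowed and
#'   left unassigned.
#' @param k Number of classes (`>= 1`).
#' @param class_labels Optional character vector of length `k`; defaults to
#'   `"S","M","L"` for `k = 3`, else `"C1".."Ck"`.
#' @return An object of class `"gap_coding"`: a list with `k`, `breakpoints`
#'   (length `k - 1`, gap midpoints), `class_labels`, `assignment` (factor of
#'   the same length as `values`) and `ranges` (per-class observed min/max).
#' @examples
#' gc <- gap_code(c(1, 2, 3, 10, 11, 20, 21), k = 3)
#' gc$breakpoints
#' @export
gap_code <- function(values, k, class_labels = NULL) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  v <- sort(unique(values[!is.na(values)]))
  if (length(v) < k) {
    stop("gap coding with k = ", k, " needs at least k distinct values, got ",
         length(v), call. = FALSE)
  }
  if (is.null(class_labels)) {
    class_labels <- if (k == 3) c("S", "M", "L") else paste0("C", seq_len(k))
  }
  stopifnot(length(class_labels) == k)
  breaks <- numeric(0)
  if (k > 1) {
    gaps <- diff(v)
    # order by decreasing width; order() is stable so earlier (smaller-value)
    # gaps win ties
    sel <- sort(order(-gaps)[seq_len(k - 1)])
    breaks <- (v[sel] + v[sel + 1]) / 2
  }
  cls <- findInterval(values, breaks) + 1L
  assignment <- factor(class_labels[cls], levels = class_labels)
  ranges <- t(vapply(seq_len(k), function(i) {
    vi <- values[!is.na(values) & as.integer(assignment) == i]
    if (length(vi) == 0) c(NA_real_, NA_real_) else range(vi)
  }, numeric(2)))
  dimnames(ranges) <- list(class_labels, c("min", "max"))
  structure(list(k = k, breakpoints = breaks, class_labels = class_labels,
                 assignment = assignment, ranges = ranges),
            class = "gap_coding")
}

#' @export
print.gap_coding <- function(x, ...) {
  cat("Gap coding with", x$k, "classes\n")
  if (length(x$breakpoints)) {
    cat("breakpoints:", paste(format(x$breakpoints), collapse = ", "), "\n")
  }
  print(table(x$assignment))
  invisible(x)
}

# canonical three-state alphabets and their two-binary-character codes
.pair_codes <- c("01", "10", "11")

pair_alphabet <- function(states) {
  u <- unique(states[!is.na(states)])
  maps <- list(c(S = "01", L = "10", M = "11"),
               c(benthic = "01", pelagic = "10", intermediate = "11"),
               c(B = "01", P = "10", I = "11"))
  hits <- vapply(maps, function(m) sum(u %in% names(m)), integer(1))
  if (max(hits) == 0) {
    stop("unknown state label(s): ", paste(u, collapse = ", "),
         "; expected the size (S/M/L) or ecotype (benthic/intermediate/",
         "pelagic) alphabet", call. = FALSE)
  }
  maps[[which.max(hits)]]
}

#' Encode a three-state character as two binary characters
#'
#' Maps the ordered three-state alphabets used here onto presence/absence
#' codes over two binary characters: the small (or benthic) extreme becomes
#' `"01"`, the large (or pelagic) extreme `"10"`, and the intermediate state
#' `"11"`. The fourth combination `"00"` is reserved for the unobserved state
#' and never assigned. This coding underlies the hidden-state
#' speciation-extinction models, where each observed move flips one binary
#' character so direct jumps between the two extremes are excluded.
#'
#' @param states Named character vector (names = species) over one of the
#'   alphabets `S/M/L`, `B/I/P` or `benthic/intermediate/pelagic`.
#' @return Named character vector of codes in `c("01","10","11")`.
#' @examples
#' encode_binary_pair(c(sp1 = "S", sp2 = "M", sp3 = "L"))
#' @export
encode_binary_pair <- function(states) {
  map <- pair_alphabet(states)
  bad <- !is.na(states) & !(states %in% names(map))
  if (any(bad)) {
    stop("states outside the alphabet for tips: ",
         paste(names(states)[bad], collapse = ", "), call. = FALSE)
  }
  out <- unname(map[states])
  names(out) <- names(states)
  out
}

#' @rdname encode_binary_pair
#' @param codes Named character vector of codes in `c("01","10","11")`.
#' @param alphabet The target labels, in the order (extreme1, extreme2,
#'   intermediate); default the size alphabet.
#' @export
decode_binary_pair <- function(codes, alphabet = c("S", "L", "M")) {
  stopifnot(length(alphabet) == 3)
  bad <- !is.na(codes) & !(codes %in% .pair_codes)
  if (any(bad)) {
    stop("invalid pair codes (00 is reserved-unobserved): ",
         paste(names(codes)[bad], collapse = ", "), call. = FALSE)
  }
  map <- stats::setNames(alphabet, .pair_codes)
  out <- unname(map[codes])
  names(out) <- names(codes)
  out
}

#' Read a tip trait table
#'
#' Expects the CSV schema
#' `species,total_length_cm,body_depth_pct,ecotype,farming` with empty fields
#' for missing values. Validates ranges and, when a tree is supplied, the
#' species/tip join.
#'
#' @param path CSV path (or a data.frame already in the schema).
#' @param tree Optional `"phylo"`; when given, species must match tip labels.
#' @return A data.frame with validated columns.
#' @export
read_trait_table <- function(path, tree = NULL) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  }
  need <- c("species", "total_length_cm", "body_depth_pct", "ecotype", "farming")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.na(df$total_length_cm) & df$total_length_cm <= 0)) {
    stop("total_length_cm must be positive", call. = FALSE)
  }
  bd <- df$body_depth_pct
  if (any(!is.na(bd) & (bd <= 0 | bd >= 100))) {
    stop("body_depth_pct must lie in (0, 100)", call. = FALSE)
  }
  ok_eco <- c("benthic", "intermediate", "pelagic")
  if (any(!is.na(df$ecotype) & !(df$ecotype %in% ok_eco))) {
    stop("ecotype must be one of ", paste(ok_eco, collapse = "/"), call. = FALSE)
  }
  if (any(!is.na(df$farming) & !(df$farming %in% c(0, 1)))) {
    stop("farming must be 0/1", call. = FALSE)
  }
  if (anyDuplicated(df$species)) stop("duplicate species rows", call. = FALSE)
  if (!is.null(tree)) {
    missing_sp <- setdiff(tree$tip.label, df$species)
    if (length(missing_sp)) {
      stop("tips absent from trait table: ",
           paste(utils::head(missing_sp, 5), collapse = ", "),
           if (length(missing_sp) > 5) ", ...", call. = FALSE)
    }
    df <- df[match(tree$tip.label, df$species), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
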