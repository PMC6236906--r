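# Genotype hidden-state space and its mapping to expected logR / logOR.
#
# A state is an unordered pair of allele copy numbers (major, minor) written
# as a string over {A, B} ("AAAB" = 3 copies of one allele, 1 of the other);
# "0" is homozygous deletion. Orientation is unidentifiable because the
# allelic signal enters the likelihood through squared logOR, so labels are
# canonicalized with the 'A' count >= the 'B' count.

#' Default 12-state genotype space labels
#'
#' All allele-specific genotypes with total copy number 0 to 5 and at most
#' one minority-allele imbalance class per total copy number: homozygous
#' deletion ("0"), hemizygous deletion LOH ("A"), copy-neutral LOH ("AA"),
#' diploid heterozygous ("AB"), single-allele gain ("AAB"), amplified LOH
#' ("AAA", "AAAA", "AAAAA"), allele-specific amplification ("AAAB",
#' "AAAAB"), balanced amplification ("AABB") and unbalanced amplification
#' ("AAABB").
#' @export
GENOTYPES_12 <- c("0", "A", "AA", "AB", "AAB", "AAA",
                  "AAAB", "AABB", "AAAA", "AAAAB", "AAABB", "AAAAA")

#' Floor (log2 units) for the expected logR of a homozygous deletion in a
#' 100\% pure tumor, where the analytic value is -Inf.
#' @export
LOGR_FLOOR <- -20

parse_genotype_label <- function(label) {
  if (identical(label, "0")) return(c(major = 0L, minor = 0L))
  if (!nzchar(label) || !grepl("^[AB]+$", label)) {
    stop("unparseable genotype label: '", label,
         "' (expected a string over {A,B}, or \"0\")", call. = FALSE)
  }
  chars <- strsplit(label, "")[[1]]
  nA <- sum(chars == "A")
  nB <- sum(chars == "B")
  c(major = as.integer(max(nA, nB)), minor = as.integer(min(nA, nB)))
}

canonical_label <- function(major, minor) {
  if (major == 0L && minor == 0L) return("0")
  paste0(strrep("A", major), strrep("B", minor))
}

#' Build a genotype state space
#'
#' Parses genotype labels into (major, minor) allele copy numbers and
#' returns an ordered state space. Labels are canonicalized so that the
#' count of 'A' is the larger allele count; `"0"` denotes homozygous
#' deletion, with zero copies of both alleles.
#'
#' @param labels Character vector of genotype labels over `{A,B}` (or
#'   `"0"`). Defaults to the full 12-state space [GENOTYPES_12].
#' @param normal_cn Integer copy number of the contaminating normal cells,
#'   default 2 (override for sex chromosomes).
#' @return A `state_space` object: a data frame with one row per state and
#'   columns `index` (1-based rank), `label`, `total_cn`, `major_cn`,
#'   `minor_cn`, carrying `normal_cn` as an attribute.
#' @examples
#' genotype_states()                 # the default 12 states
#' genotype_states(c("A", "AB"))    # a restricted 2-state space
#' @export
genotype_states <- function(labels = GENOTYPES_12, normal_cn = 2L) {
  if (length(labels) < 1L) stop("need at least one genotype label")
  counts <- vapply(labels, parse_genotype_label, integer(2))
  canon <- mapply(canonical_label, counts["major", ], counts["minor", ])
  if (anyDuplicated(canon)) {
    stop("duplicate genotype labels after canonicalization: ",
         paste(canon[duplicated(canon)], collapse = ", "))
  }
  ss <- data.frame(
    index    = seq_along(labels),
    label    = unname(canon),
    total_cn = unname(counts["major", ] + counts["minor", ]),
    major_cn = unname(counts["major", ]),
    minor_cn = unname(counts["minor", ]),
    stringsAsFactors = FALSE
  )
  attr(ss, "normal_cn") <- as.integer(normal_cn)
  class(ss) <- c("state_space", "data.frame")
  ss
}

#' @export
print.state_space <- function(x, ...) {
  cat("Genotype state space with", nrow(x), "states (normal CN =",
      attr(x, "normal_cn"), ")\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

normal_cn_of <- function(space) {
  cn <- attr(space, "normal_cn")
  if (is.null(cn)) 2L else cn
}

#' Expected logR of genotype states
#'
#' The expected log2 tumor/normal depth ratio for a tumor of purity
#' \eqn{\alpha} and ploidy \eqn{\psi}:
#' \deqn{\mu_j = \log_2\{[(1-\alpha) C_N + \alpha C_{T,j}]/\psi\}.}
#' The only degenerate case is a homozygous deletion in a 100\% pure tumor
#' (argument of the log is 0); it is floored at [LOGR_FLOOR] so emission
#' densities stay finite.
#'
#' @param space A `state_space` (or any data frame with a `total_cn`
#'   column).
#' @param purity Tumor purity \eqn{\alpha} in (0, 1].
#' @param ploidy Tumor ploidy \eqn{\psi > 0}.
#' @param normal_cn Normal-cell copy number; defaults to the space's
#'   attribute.
#' @return Numeric vector of expected logR, one per state.
#' @export
expected_logR <- function(space, purity, ploidy, normal_cn = normal_cn_of(space)) {
  stopifnot(purity > 0, purity <= 1, ploidy > 0)
  arg <- ((1 - purity) * normal_cn + purity * space$total_cn) / ploidy
  out <- ifelse(arg > 0, log2(arg), LOGR_FLOOR)
  pmax(out, LOGR_FLOOR)
}

#' Expected logOR of genotype states
#'
#' The expected natural-log allelic odds ratio of tumor versus normal:
#' \deqn{\zeta_j = \log\{[(1-\alpha) + \alpha m_j]/[(1-\alpha) + \alpha p_j]\},}
#' with \eqn{m_j \ge p_j} the major/minor allele copy numbers, so
#' \eqn{\zeta_j \ge 0} always. For a pure tumor (\eqn{\alpha = 1}) with
#' both alleles deleted the 0/0 limit is defined as 0 (the symmetric
#' \eqn{m = p} case); a pure tumor with only the minor allele lost gives
#' `Inf` (never reached during fitting, where purity is boxed below 1).
#'
#' @inheritParams expected_logR
#' @return Numeric vector of expected logOR, one per state.
#' @export
expected_logOR <- function(space, purity) {
  stopifnot(purity > 0, purity <= 1)
  num <- (1 - purity) + purity * space$major_cn
  den <- (1 - purity) + purity * space$minor_cn
  out <- ifelse(num == 0 & den == 0, 0, log(num / den))
  out
}
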