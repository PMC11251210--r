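#' Genetic map as constant cM/Mb conversion ratios
#'
#' Physical distances are converted to genetic distances with a constant
#' cM/Mb ratio per chromosome (no piecewise recombination map), plus a
#' genome-wide default for chromosomes without an override.
#'
#' @param default_ratio Genome-wide cM/Mb fallback (positive), or `NULL`
#'   if every chromosome will have an override.
#' @param ratios Named numeric vector of per-chromosome cM/Mb overrides.
#' @return Object of class `genetic_map`.
#' @export
genetic_map <- function(default_ratio = NULL, ratios = NULL) {
  if (!is.null(default_ratio)) {
    if (!is.numeric(default_ratio) || length(default_ratio) != 1L ||
        !is.finite(default_ratio) || default_ratio <= 0)
      stop("default_ratio must be a single positive number (cM/Mb)")
  }
  if (!is.null(ratios)) {
    ratios <- unlist(ratios)
    if (is.null(names(ratios)) || any(names(ratios) == ""))
      stop("per-chromosome ratios must be named by chromosome")
    if (!is.numeric(ratios) || any(!is.finite(ratios)) || any(ratios <= 0))
      stop("cM/Mb ratios must be positive finite numbers")
  }
  if (is.null(default_ratio) && (is.null(ratios) || length(ratios) == 0L))
    stop("a genetic map needs a default ratio or per-chromosome ratios")
  structure(list(default_ratio = default_ratio, ratios = ratios),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map (cM/Mb):",
      if (is.null(x$default_ratio)) "no default" else
        sprintf("default %.4g", x$default_ratio),
      if (length(x$ratios)) sprintf("+ %d override(s)", length(x$ratios))
      else "", "\n")
  invisible(x)
}

#' Load a genetic-map configuration file
#'
#' Plain-text key-value format, one entry per line: a chromosome label (or
#' the keyword `default`) followed by its cM/Mb ratio, separated by
#' whitespace, `=` or `:`. Blank lines and `#` comments are ignored.
#'
#' @param path Path to the config file.
#' @return A [genetic_map()].
#' @export
load_map <- function(path) {
  if (!file.exists(path)) stop("map config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  default_ratio <- NULL
  ratios <- numeric(0)
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:]=:]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L)
      stop("malformed map config line: ", ln)
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val) || val <= 0)
      stop("cM/Mb ratio must be a positive number, got: ", ln)
    if (tolower(parts[1]) == "default") default_ratio <- val
    else ratios[parts[1]] <- val
  }
  genetic_map(default_ratio = default_ratio,
              ratios = if (length(ratios)) ratios else NULL)
}

#' Convert physical distance to genetic distance in Morgans
#'
#' `c = bp_dist / 1e6 * ratio(chrom) / 100`: bp to Mb, Mb to cM via the
#' chromosome's cM/Mb ratio, cM to Morgans. Vectorized over `chrom` and
#' `bp_dist` (recycled against each other).
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome label(s).
#' @param bp_dist Physical distance(s) in bp, >= 0.
#' @return Genetic distance(s) in Morgans.
#' @export
bp_to_morgans <- function(map, chrom, bp_dist) {
  stopifnot(inherits(map, "genetic_map"))
  if (any(bp_dist < 0, na.rm = TRUE))
    stop("bp_dist must be >= 0")
  chrom <- as.character(chrom)
  ratio <- rep(if (is.null(map$default_ratio)) NA_real_ else map$default_ratio,
               length.out = max(length(chrom), length(bp_dist)))
  chrom <- rep(chrom, length.out = length(ratio))
  if (length(map$ratios)) {
    hit <- match(chrom, names(map$ratios))
    ratio[!is.na(hit)] <- map$ratios[hit[!is.na(hit)]]
  }
  if (any(is.na(ratio)))
    stop("no cM/Mb ratio for chromosome(s) ",
         paste(unique(chrom[is.na(ratio)]), collapse = ", "),
         " and no default set")
  bp_dist / 1e6 * ratio / 100
}
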