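# Internal helpers shared across modules.

# IUPAC ambiguity codes (degenerate, excluding N which is always missing)
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Render a proportion as a percentage string
#'
#' Formats an uncorrected p-distance (a fraction in \code{[0, 1]}) as a
#' percentage at one decimal place using round-half-up, the convention used
#' when reporting barcode divergences (e.g. 16/658 renders as \code{"2.4 \%"}).
#' Base R's \code{round()} rounds half to even, which would turn 2.25 into
#' 2.2; divergence percentages are conventionally reported half-up.
#'
#' @param p Numeric vector of fractions in \code{[0, 1]}.
#' @param digits Decimal places (default 1).
#' @return Character vector like \code{"2.4 \%"}.
#' @examples
#' render_percent(16 / 658)
#' @export
render_percent <- function(p, digits = 1) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  v <- round_half_up(p * 100, digits)
  paste0(formatC(v, format = "f", digits = digits), " %")
}

# round-half-up with a tiny epsilon guard against binary representation of
# values that are exact halves in decimal (e.g. 2.25 stored as 2.2499999...)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# split residue strings into an n x L character matrix
seq_matrix <- function(sequences) {
  stopifnot(length(sequences) > 0)
  L <- unique(nchar(sequences))
  if (length(L) != 1) {
    stop("sequences have unequal lengths: ", paste(sort(L), collapse = ", "),
         call. = FALSE)
  }
  matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
         nrow = length(sequences), ncol = L, byrow = TRUE,
         dimnames = list(names(sequences), NULL))
}

# logical matrix of residues treated as missing under a site policy:
# gaps and N always; IUPAC ambiguity codes when ambiguity = "treat_as_missing"
missing_mask <- function(char_mat, policy) {
  masked_states <- c("-", "N")
  if (policy$ambiguity == "treat_as_missing") {
    masked_states <- c(masked_states, IUPAC_AMBIG)
  }
  matrix(char_mat %in% masked_states, nrow = nrow(char_mat))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
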