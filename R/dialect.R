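#' @keywords internal
"_PACKAGE"

## Shared antiSMASH 5.x dialect vocabulary.
##
## The fixture writer and the region parser both draw on this single table so
## the two sides of the dialect cannot drift apart: every domain kind has one
## canonical aSDomain label (used when writing) and a set of accepted aliases
## (used when parsing).

#' Domain kinds understood by the reconstruction calculus
#'
#' The 20 functional domain kinds of NRPS / type 1 PKS / trans-AT PKS assembly
#' lines, plus `UNKNOWN` for annotated domains outside this vocabulary.
#'
#' @return Character vector of domain kind codes.
#' @export
domain_kinds <- function() {
  c("A", "ACP", "AT", "C", "CAL", "cMT", "Cy", "DH", "E", "ECH", "ER",
    "FkbH", "GNAT", "KR", "KS", "nMT", "oMT", "PCP", "TD", "TE", "UNKNOWN")
}

# canonical aSDomain label written for each kind
.dialect_write_label <- c(
  A    = "AMP-binding",
  ACP  = "PP-binding",
  AT   = "PKS_AT",
  C    = "Condensation_LCL",
  CAL  = "CAL_domain",
  cMT  = "cMT",
  Cy   = "Heterocyclization",
  DH   = "PKS_DH",
  E    = "Epimerization",
  ECH  = "ECH",
  ER   = "PKS_ER",
  FkbH = "FkbH",
  GNAT = "GNAT",
  KR   = "PKS_KR",
  KS   = "PKS_KS",
  nMT  = "nMT",
  oMT  = "oMT",
  PCP  = "PCP",
  TD   = "Thioester-redct",
  TE   = "Thioesterase"
)

# accepted aSDomain labels -> kind (antiSMASH 5.x vocabulary plus common
# variants; anything else degrades to UNKNOWN, never dropped)
.dialect_parse_label <- c(
  "AMP-binding"          = "A",
  "A-OX"                 = "A",
  "PP-binding"           = "ACP",
  "ACP"                  = "ACP",
  "ACP_beta"             = "ACP",
  "PKS_PP"               = "ACP",
  "PKS_AT"               = "AT",
  "Condensation"         = "C",
  "Condensation_LCL"     = "C",
  "Condensation_DCL"     = "C",
  "Condensation_Starter" = "C",
  "Condensation_Dual"    = "C",
  "Cglyc"                = "C",
  "CAL_domain"           = "CAL",
  "cMT"                  = "cMT",
  "Heterocyclization"    = "Cy",
  "Cy"                   = "Cy",
  "PKS_DH"               = "DH",
  "PKS_DH2"              = "DH",
  "PKS_DHt"              = "DH",
  "Epimerization"        = "E",
  "ECH"                  = "ECH",
  "PKS_ER"               = "ER",
  "FkbH"                 = "FkbH",
  "GNAT"                 = "GNAT",
  "PKS_KR"               = "KR",
  "PKS_KS"               = "KS",
  "nMT"                  = "nMT",
  "oMT"                  = "oMT",
  "PCP"                  = "PCP",
  "Thioester-redct"      = "TD",
  "TD"                   = "TD",
  "Thioesterase"         = "TE"
)

# region /product labels -> cluster class
.dialect_class <- c(
  "NRPS"        = "NRPS",
  "NRPS-like"   = "NRPS",
  "T1PKS"       = "T1PKS",
  "transAT-PKS" = "transAT-PKS",
  "transAT-PKS-like" = "transAT-PKS"
)

.kind_from_label <- function(label) {
  kind <- unname(.dialect_parse_label[label])
  kind[is.na(kind)] <- "UNKNOWN"
  kind
}

.label_from_kind <- function(kind) {
  lab <- unname(.dialect_write_label[kind])
  lab[is.na(lab)] <- "Unknown-domain"
  lab
}
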