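# Built-in fixture networks.

#' The Tyson (1991) six-variable cell-cycle network
#'
#' The classic cyclin/cdc2 oscillator: cyclin (Y) is synthesized de
#' novo, binds phosphorylated cdc2 (CP) to form preMPF (pM), which is
#' dephosphorylated to active MPF (M); MPF destruction releases cdc2
#' (C2) and phosphorylated cyclin (YP), which is degraded.  Six
#' reactive species, nine irreversible reactions, one inflow.  Reaction
#' ids follow the SBML numbering (`Reaction1` ... `Reaction9`); labels
#' carry the original paper numbering (R1 ... R9).
#'
#' @return a `reaction_network` with 6 reactive species and 9
#'   reactions.
#' @export
tyson_fixture <- function() {
  sp <- list(
    species("C2", "cdc2"),
    species("CP", "cdc2-P"),
    species("pM", "preMPF (P-cyclin-cdc2-P)"),
    species("M", "active MPF (P-cyclin-cdc2)"),
    species("Y", "cyclin"),
    species("YP", "cyclin-P"),
    species("EmptySet", "EmptySet", is_boundary = TRUE)
  )
  rx <- list(
    reaction("Reaction1", c(M = 1L), c(C2 = 1L, YP = 1L),
             label = "R6: destruction of active MPF"),
    reaction("Reaction2", c(C2 = 1L), c(CP = 1L),
             label = "R8: phosphorylation of cdc2"),
    reaction("Reaction3", c(CP = 1L), c(C2 = 1L),
             label = "R9: reversion of cdc2 phosphorylation"),
    reaction("Reaction4", c(CP = 1L, Y = 1L), c(pM = 1L),
             label = "R3: cdc2-P + cyclin to preMPF"),
    reaction("Reaction5", c(M = 1L), c(pM = 1L),
             label = "R5: opposition of MPF activation"),
    reaction("Reaction6", c(EmptySet = 1L), c(Y = 1L),
             label = "R1: de novo synthesis of cyclin"),
    reaction("Reaction7", c(Y = 1L), c(EmptySet = 1L),
             label = "R2: cyclin decay"),
    reaction("Reaction8", c(YP = 1L), c(EmptySet = 1L),
             label = "R7: proteolysis of phosphorylated cyclin"),
    reaction("Reaction9", c(pM = 1L), c(M = 1L),
             label = "R4: dephosphorylation of cdc2 (MPF activation)")
  )
  build_network(sp, rx)
}

#' Synthetic stand-in for the Markevich (2004) elementary MAPK model
#'
#' A 16-species / 27-reaction dual phosphorylation-dephosphorylation
#' cycle of a MAP kinase M, reconstructed to the size and mechanism the
#' original elementary-step model describes: the kinase MAPKK
#' phosphorylates M on two sites in random order (via MpY and MpT), the
#' phosphatase MKP3 removes them again, and both enzymes form dead-end
#' complexes (M_MKP3, Mpp_MAPKK) with the "wrong" substrate.  This is a
#' SYNTHETIC reconstruction, not the BioModels SBML: the public model
#' file cannot be redistributed here, so organizational results on this
#' network are a stand-in for the published analysis.
#'
#' @return a `reaction_network` with 16 reactive species and 27
#'   reactions (no inflows; the system is mass closed).
#' @export
markevich_synthetic_fixture <- function() {
  txt <- c(
    "# kinase side: random-order dual phosphorylation",
    "R1: M + MAPKK -> M_MAPKK",
    "R2: M_MAPKK -> M + MAPKK",
    "R3: M_MAPKK -> MpY + MAPKK",
    "R4: M_MAPKK -> MpT + MAPKK",
    "R5: MpY + MAPKK -> MpY_MAPKK",
    "R6: MpY_MAPKK -> MpY + MAPKK",
    "R7: MpY_MAPKK -> Mpp + MAPKK",
    "R8: MpT + MAPKK -> MpT_MAPKK",
    "R9: MpT_MAPKK -> MpT + MAPKK",
    "R10: MpT_MAPKK -> Mpp_MAPKK_star",
    "R11: Mpp_MAPKK_star -> Mpp + MAPKK",
    "R12: Mpp_MAPKK_star -> MpT_MAPKK",
    "# phosphatase side",
    "R13: Mpp + MKP3 -> Mpp_MKP3",
    "R14: Mpp_MKP3 -> Mpp + MKP3",
    "R15: Mpp_MKP3 -> MpY_MKP3_star",
    "R16: MpY_MKP3_star -> MpY + MKP3",
    "R17: Mpp_MKP3 -> MpT + MKP3",
    "R18: MpY + MKP3 -> MpY_MKP3",
    "R19: MpY_MKP3 -> MpY + MKP3",
    "R20: MpY_MKP3 -> M + MKP3",
    "R21: MpT + MKP3 -> MpT_MKP3",
    "R22: MpT_MKP3 -> MpT + MKP3",
    "R23: MpT_MKP3 -> M + MKP3",
    "# dead-end enzyme-substrate complexes",
    "R24: M + MKP3 -> M_MKP3",
    "R25: M_MKP3 -> M + MKP3",
    "R26: Mpp + MAPKK -> Mpp_MAPKK",
    "R27: Mpp_MAPKK -> Mpp + MAPKK"
  )
  read_reaction_text(paste(txt, collapse = "\n"))
}
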