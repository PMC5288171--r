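#' Published verification-study statistics for the endometrial-cancer panel
#'
#' The per-peptide verification statistics of the 48 significant peptides
#' (26 proteins) from the uterine-aspirate LC-PRM study: fold change,
#' BH-adjusted p-value, light/heavy ratio quartiles in the tumor (n = 20) and
#' control (n = 18) groups, AUC, the reported sensitivity/specificity
#' operating point, and sensitivity at 95\% specificity. The group quartiles
#' parameterize the synthetic cohort generator (see
#' \code{\link{defaultPeptidePanel}}), and the AUC column is the recovery
#' target of the simulation-based checks.
#'
#' @return data.frame with columns \code{protein}, \code{peptide}, \code{fc},
#'   \code{adj_p}, \code{tumor_q1}, \code{tumor_q3}, \code{control_q1},
#'   \code{control_q3}, \code{auc}, \code{sensitivity}, \code{specificity},
#'   \code{sens_at_95spec}.
#' @examples
#' tab <- table1Stats()
#' subset(tab, peptide == "IANVFTNAFR")
#' @export
table1Stats <- function() {
  txt <- "protein|peptide|fc|adj_p|tumor_q1|tumor_q3|control_q1|control_q3|auc|sensitivity|specificity|sens_at_95spec
PERM|IANVFTNAFR|14.1|6e-05|0.56|2.18|0.04|0.13|0.97|95|89|80
PERM|VVLEGGIDPILR|13.3|1e-04|0.94|4.00|0.08|0.29|0.95|95|89|70
CADH1|VFYSITGQGADTPPVGVFIIER|3.8|9e-05|0.55|1.27|0.11|0.28|0.94|95|89|85
CADH1|NLVQIK|3.3|2e-04|0.44|1.09|0.12|0.25|0.93|85|94|85
SPIT1|SFVYGGCLGNK|3.3|1e-04|0.33|0.66|0.07|0.20|0.93|95|94|95
SPIT1|WYYDPTEQICK|3.3|1e-04|0.30|0.55|0.06|0.18|0.93|90|94|90
ENOA|YISPDQLADLYK|3.8|1e-04|13.43|25.66|2.89|5.76|0.92|75|94|75
ENOA|TIAPALVSK|4.0|2e-04|6.85|18.62|1.51|3.23|0.89|80|83|70
MMP9|SLGPALLLLQK|5.7|1e-04|0.52|2.42|0.05|0.19|0.91|95|83|60
MMP9|AFALWSAVTPLTFTR|5.5|1e-04|0.35|1.60|0.03|0.14|0.91|90|83|60
LDHA|LVIITAGAR|6.2|1e-04|3.55|7.23|0.26|0.78|0.91|85|89|65
LDHA|VTLTSEEEAR|5.7|1e-04|11.32|22.52|0.94|2.75|0.91|85|89|60
CASP3|SGTDVDAANLR|4.9|2e-04|0.04|0.11|0.00|0.02|0.91|90|89|65
KPYM_M1M2|NTGIICTIGPASR|5.4|1e-04|10.82|41.42|1.29|5.52|0.91|85|89|75
KPYM_M1M3|APIIAVTR|3.1|1e-02|0.43|1.39|0.10|0.51|0.75|60|89|50
PRDX1|LVQAFQFTDK|4.2|2e-04|11.08|27.24|2.06|7.32|0.90|75|94|75
PRDX1|ADEGISFR|4.2|2e-04|0.80|1.93|0.16|0.52|0.90|75|94|75
OSTP_A|ANDESNEHSDVIDSQELSK|11.4|2e-04|0.11|0.44|0.00|0.05|0.90|80|94|80
OSTP_ABD|AIPVAQDLNAPSDWDSR|9.0|4e-04|0.10|0.56|0.01|0.07|0.87|80|83|50
PDIA1|ILEFFGLK|3.3|3e-04|0.16|0.41|0.03|0.13|0.89|75|89|65
PDIA1|ALAPEYAK|3.0|3e-04|0.26|0.65|0.06|0.22|0.88|75|89|65
NAMPT|YLLETSGNLDGLEYK|4.2|3e-04|0.31|1.04|0.01|0.16|0.88|90|83|40
NAMPT|YDGHLPIEIK|4.0|3e-04|0.57|2.05|0.08|0.32|0.88|90|83|40
MIF|VYINYYDMNAANVGWNNSTFA|4.2|3e-04|0.91|1.89|0.05|0.45|0.88|75|94|75
MIF|LLCGLLAER|3.1|3e-04|45.14|98.96|11.49|27.40|0.87|70|94|70
CTNB1|LLNDEDQVVVNK|4.2|3e-04|0.06|0.21|0.00|0.04|0.88|85|89|70
CTNB1|LVQLLVR|4.2|3e-04|0.07|0.27|0.00|0.04|0.87|85|89|65
K2C8|LSELEAALQR|3.6|3e-04|1.04|2.99|0.17|0.92|0.88|95|67|65
K2C8|WSLLQQQK|3.1|6e-04|0.45|1.25|0.09|0.45|0.85|60|94|60
ANXA2|GVDEVTIVNILTNR|4.8|4e-04|5.60|20.24|1.36|4.74|0.87|75|89|45
ANXA2|QDIAFAYQR|5.1|5e-04|0.26|1.07|0.05|0.25|0.86|95|61|50
CAPG|EGNPEEDLTADK|3.6|5e-04|0.32|1.11|0.05|0.17|0.85|85|83|45
CAPG|YQEGGVESAFHK|3.5|6e-04|0.44|1.63|0.08|0.27|0.85|80|83|45
FABP5|LVVECVMNNVTCTR|3.9|6e-04|2.27|8.29|0.84|1.56|0.85|90|78|45
FABP5|ELGVGIALR|3.6|6e-04|0.03|0.10|0.01|0.02|0.85|90|78|45
MUC1|QGGFLGLSNIK|3.6|1e-03|5.11|12.65|1.18|4.04|0.84|85|78|45
CAYP1|SGDGVVTVDDLR|3.4|1e-03|4.04|19.35|1.16|3.48|0.83|85|78|45
XPO2|ANIVHLMLSSPEQIQK|4.0|1e-03|0.05|0.19|0.00|0.04|0.83|75|89|25
XPO2|LLQTDDEEEAGLLELLK|4.4|2e-03|0.04|0.22|0.00|0.04|0.81|70|89|40
NGAL|VPLQQNFQDNQFQGK|5.0|1e-03|2.19|8.19|0.29|2.03|0.83|75|89|35
NGAL|ELTSELK|4.4|4e-03|2.09|9.13|0.35|2.04|0.79|70|83|30
SG2A1|ELLQEFIDSDAAAEAMGK|3.3|3e-03|0.15|0.35|0.02|0.17|0.80|90|72|30
SG2A1|TINSDISIPEYK|3.2|5e-03|0.12|0.30|0.02|0.14|0.78|90|67|40
ANXA1|DITSDTSGDFR|4.8|3e-03|1.12|4.44|0.33|1.16|0.80|60|100|60
ANXA1|GGPGSAVSPYPTFNPSSDVAALHK|3.9|7e-03|1.33|6.02|0.51|2.02|0.77|55|100|55
HSPB1|LFDQAFGLPR|3.6|4e-03|1.31|7.31|0.60|1.78|0.79|85|67|40
HSPB1|LATQSNEITIPVTFESR|3.1|4e-03|2.74|13.66|1.27|3.67|0.79|85|67|40
PIGR|VYTVDLGR|3.4|7e-03|38.67|128.80|15.43|37.38|0.77|80|78|30"
  utils::read.delim(text = txt, sep = "|", stringsAsFactors = FALSE)
}
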