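# Scratch script used to capture real console output for the README
# worked example. Not part of the installed package.
library(repgwas)

spec <- design_spec(t = 3, rho = 0.4, alpha = 1e-8, power = 0.8, q = 0.005)
n3 <- analytic_sample_size(spec)
print(n3)
print(design_savings(spec))

set.seed(42)
beta <- effect_size_from_q(0.005, residual_variance = 1, p = 0.3)
cat(sprintf("beta at MAF 0.3: %.4f\n", beta))
d <- simulate_cohort(sim_spec(n = 2000, t = 3, maf = 0.3, beta = 0.25,
                              sigma_c2 = 0.4, sigma_e2 = 0.6,
                              dropout = "kare"))
fit <- fit_gls_longitudinal(d)
print(coef_term(fit, "SNP"))
print(round(fit$sigma, 3))

G <- cbind(causal = d$snp,
           matrix(rbinom(2000 * 999, 2, 0.3), 2000, 999,
                  dimnames = list(NULL, paste0("null", 1:999))))
scan <- gwas_scan(d, G, model = "longitudinal")
print(head(scan[order(scan$p), c("snp", "beta", "se", "p")], 3))
gc_rep <- genomic_control(p = scan$p)
cat(sprintf("genomic-control lambda: %.3f\n", gc_rep$lambda))

print(fisher_combine(c(4.46e-9, 3.58e-1)))
print(liptak_combine(c(4.46e-9, 3.58e-1), n = c(8841, 3703)))
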