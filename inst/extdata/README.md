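# extdata

`benchmark_sim_1.csv` ... `benchmark_sim_5.csv` are five frozen synthetic
benchmark datasets drawn from the package's own incidence generative model
(`simulate_incidence()`) at varying cohort sizes, variance components and
effect patterns. They are used by the test suite to cross-validate the
package's REML mixed-model estimator (coefficients, standard errors,
Satterthwaite degrees of freedom) against an independent established
implementation. Columns follow the long-format incidence CSV contract.
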