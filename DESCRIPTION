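Package: fortisim
Title: Simulation of Micronutrient Intervention Scenarios for Women of
    Reproductive Age
Version: 0.1.0
Authors@R:
    person("fortisim", "maintainers", email = "fortisim@example.org",
           role = c("aut", "cre"))
Description: Builds daily diet scenarios for women of reproductive age in
    West African settings, layers micronutrient interventions on them
    (mass fortification of salt, oil and wheat flour; biofortified crops;
    iron-folic-acid and high-dose vitamin A supplementation; micronutrient-
    rich food swaps), totals daily intake of six tracked micronutrients
    (iron, zinc, vitamin A, niacin, folate, iodine), and evaluates coverage
    against EAR/RNI/UL reference values to flag inadequate intake and risk
    of excess. Includes calibrated Benin/Ghana scenario fixtures, a
    synthetic scenario generator with an independent brute-force intake
    oracle, report rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
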