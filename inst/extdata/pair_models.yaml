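# Registry of published Gaussian distance-distribution parameter sets for
# the doubly spin-labeled cTnI/cTnC constructs (i, i+4 labeling of the cTnI
# N-extension), used to generate synthetic benchmark fixtures.
# r, dr in nm (dr = FWHM); fractions in percent; f_non is the
# non-interacting / >2.5 nm pool.  chi2 values are the published
# goodness-of-fit numbers and are carried for reference only (their
# normalization is instrument-specific and not reproduced here).
pairs:
  - {protein: "cTnI(15/19MSL)",        kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 5.6, r: [1.73], dr: [2.0],  f: [70], f_non: 30},
     two_gaussian: {chi2: 3.7, r: [0.89, 1.58], dr: [0.13, 0.90], f: [23, 49], f_non: 27}}
  - {protein: "cTnI(15/19MSL)+cTnC",   kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 18,  r: [2.09], dr: [2.0],  f: [70], f_non: 30},
     two_gaussian: {chi2: 12,  r: [0.88, 2.04], dr: [0.05, 1.2],  f: [18, 55], f_non: 27}}
  - {protein: "cTnI(23/27MSL)",        kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 8.8, r: [2.01], dr: [2.0],  f: [68], f_non: 32},
     two_gaussian: {chi2: 7.7, r: [0.88, 2.12], dr: [0.05, 1.5],  f: [18, 56], f_non: 26}}
  - {protein: "cTnI(23/27MSL)+cTnC",   kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 9.0, r: [2.22], dr: [2.0],  f: [60], f_non: 40},
     two_gaussian: {chi2: 7.9, r: [0.90, 2.09], dr: [0.05, 1.1],  f: [12, 49], f_non: 39}}
  - {protein: "cTnI(27/31MSL)",        kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 3.1, r: [1.56], dr: [2.0],  f: [65], f_non: 35},
     two_gaussian: {chi2: 2.5, r: [0.95, 1.81], dr: [0.10, 1.2],  f: [16, 49], f_non: 35}}
  - {protein: "cTnI(27/31MSL)+cTnC",   kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 1.8, r: [1.75], dr: [2.0],  f: [71], f_non: 29},
     two_gaussian: {chi2: 1.4, r: [0.88, 1.56], dr: [0.05, 0.8],  f: [24, 47], f_non: 29}}
  - {protein: "cTnI(35/39MSL)",        kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 5.8, r: [1.79], dr: [2.0],  f: [66], f_non: 34},
     two_gaussian: {chi2: 3.6, r: [0.93, 1.94], dr: [0.12, 1.1],  f: [19, 49], f_non: 32}}
  - {protein: "cTnI(35/39MSL)+cTnC",   kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 14,  r: [2.26], dr: [2.0],  f: [61], f_non: 39},
     two_gaussian: {chi2: 7.9, r: [0.88, 1.91], dr: [0.05, 0.7],  f: [18, 37], f_non: 45}}
  - {protein: "cTnI(43/47MSL)",        kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 6.4, r: [1.59], dr: [2.0],  f: [75], f_non: 25},
     two_gaussian: {chi2: 3.3, r: [0.91, 1.85], dr: [0.08, 1.2],  f: [23, 55], f_non: 22}}
  - {protein: "cTnI(43/47MSL)+cTnC",   kcl_M: 0.2, label: MSL,
     one_gaussian: {chi2: 14,  r: [1.54], dr: [2.0],  f: [71], f_non: 29},
     two_gaussian: {chi2: 5.4, r: [0.88, 1.93], dr: [0.05, 1.5],  f: [25, 54], f_non: 21}}
  - {protein: "cTnI(15/19MTSL)",       kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 4.8, r: [1.00], dr: [2.0],  f: [67], f_non: 33},
     two_gaussian: {chi2: 4.2, r: [0.90, 0.91], dr: [0.04, 2.0],  f: [6, 61],  f_non: 33}}
  - {protein: "cTnI(15/19MTSL)+cTnC",  kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 2.4, r: [0.80], dr: [1.7],  f: [67], f_non: 33},
     two_gaussian: {chi2: 1.6, r: [0.90, 0.94], dr: [0.04, 1.74], f: [11, 54], f_non: 35}}
  - {protein: "cTnI(23/27MTSL)",       kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 4.3, r: [0.80], dr: [2.0],  f: [43], f_non: 57},
     two_gaussian: {chi2: 3.0, r: [0.89, 1.77], dr: [0.05, 0.86], f: [16, 32], f_non: 52}}
  - {protein: "cTnI(23/27MTSL)+cTnC",  kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 1.9, r: [1.19], dr: [1.02], f: [58], f_non: 42},
     two_gaussian: {chi2: 1.5, r: [0.94, 1.40], dr: [0.06, 0.48], f: [15, 40], f_non: 45}}
  - {protein: "cTnI(27/31MTSL)",       kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 3.1, r: [0.82], dr: [2.0],  f: [66], f_non: 34},
     two_gaussian: {chi2: 2.5, r: [0.90, 1.47], dr: [0.08, 0.65], f: [19, 42], f_non: 39}}
  - {protein: "cTnI(27/31MTSL)+cTnC",  kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 1.8, r: [0.80], dr: [1.62], f: [63], f_non: 37},
     two_gaussian: {chi2: 1.4, r: [0.92, 1.41], dr: [0.05, 0.66], f: [21, 37], f_non: 42}}
  - {protein: "cTnI(35/39MTSL)",       kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 2.4, r: [2.76], dr: [2.0],  f: [65], f_non: 35},
     two_gaussian: {chi2: 1.5, r: [0.94, 2.09], dr: [0.05, 1.33], f: [10, 39], f_non: 51}}
  - {protein: "cTnI(35/39MTSL)+cTnC",  kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 4.6, r: [1.42], dr: [2.0],  f: [46], f_non: 54},
     two_gaussian: {chi2: 3.7, r: [0.89, 2.28], dr: [0.05, 1.99], f: [19, 44], f_non: 37}}
  - {protein: "cTnI(43/47MTSL)",       kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 3.0, r: [0.80], dr: [1.54], f: [65], f_non: 35},
     two_gaussian: {chi2: 1.6, r: [0.91, 1.18], dr: [0.06, 1.34], f: [21, 50], f_non: 29}}
  - {protein: "cTnI(43/47MTSL)+cTnC",  kcl_M: 0.1, label: MTSL,
     one_gaussian: {chi2: 6.4, r: [0.80], dr: [0.67], f: [75], f_non: 25},
     two_gaussian: {chi2: 2.3, r: [0.91, 1.21], dr: [0.10, 1.32], f: [48, 29], f_non: 23}}
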