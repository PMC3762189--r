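# Default rate constants for the branching-nucleation reaction network.
#
# Units as conventionally tabulated: k_on in 1/(M s) for bimolecular
# reactions and 1/s for unimolecular ones; k_off in 1/s; kd_um in uM.
# Bimolecular constants are converted to 1/(uM s) when a network is built.
# k_on values given as [lo, hi] are condition-adjusted ranges; the package
# default for each is recorded under `default`.
#
# kd_um is the printed equilibrium constant and is metadata only; rates are
# what the simulator uses.  For reaction 16 the printed K_D (0.028 uM) is
# inconsistent with k_off/k_on (0.036 uM); the kinetic constants are kept
# and the discrepancy is flagged with kd_inconsistent.  The same holds
# for reactions 14/20 (k_off/k_on = 0.09 uM vs tabulated 0.009 uM).
reactions:
  - {id: 1,  description: "Actin dimerization",                                             k_on: 1.98e7, k_off: 5.26e7, kd_um: 2.6e6,  bimolecular: true,  source: "Mullins 1998"}
  - {id: 2,  description: "Actin trimerization",                                            k_on: 1.16e7, k_off: 4.07e5, kd_um: 3.5e4,  bimolecular: true,  source: "Mullins 1998"}
  - {id: 3,  description: "Spontaneous nucleation",                                         k_on: [1110, 1220], default: 1165, bimolecular: false, source: "this model"}
  - {id: 4,  description: "Barbed end elongation",                                          k_on: 1.16e7, k_off: 1.4,             bimolecular: true,  source: "Pollard 1986"}
  - {id: 5,  description: "Barbed end elongation, actin monomer bound to GST-VCA",          k_on: 1.16e7, k_off: 1.4,             bimolecular: true,  source: "Pollard 1986, Higgs 1999"}
  - {id: 6,  description: "Barbed end elongation, two actin monomers bound to GST-VCA",     k_on: 1.16e7, k_off: 1.4,             bimolecular: true,  source: "Pollard 1986, Higgs 1999"}
  - {id: 7,  description: "Actin monomer binds GST-VCA",                                    k_on: 5.0e6,  k_off: 3,      kd_um: 0.6,    bimolecular: true,  source: "Marchand 2001, Beltzner 2008"}
  - {id: 8,  description: "Actin monomer binds GST-VCA with bound actin",                   k_on: 5.0e6,  k_off: 3,      kd_um: 0.6,    bimolecular: true,  source: "Marchand 2001, Beltzner 2008"}
  - {id: 9,  description: "Actin monomer binds GST-VCA:actin2",                             k_on: 4.2e4,  k_off: 74.4,   kd_um: 1.8e3,  bimolecular: true,  source: "this model"}
  - {id: 10, description: "Actin monomer binds GST-VCA:actin3",                             k_on: 1.5e7,  k_off: 1.04,   kd_um: 0.069,  bimolecular: true,  source: "this model"}
  - {id: 11, description: "Actin monomer binds GST-VCA:actin4",                             k_on: 2.0e7,  k_off: 0.062,  kd_um: 0.003,  bimolecular: true,  source: "this model"}
  - {id: 12, description: "GST-VCA nucleation",                                             k_on: 6.1e-8,                         bimolecular: false, source: "this model"}
  - {id: 13, description: "Arp2/3 binds actin filament",                                    k_on: 1.37e6, k_off: 1.23,   kd_um: 0.9,    bimolecular: true,  source: "Hetrick 2013"}
  - {id: 14, description: "GST-VCA binds Arp2/3",                                           k_on: 0.8e6,  k_off: 0.072,  kd_um: 0.009,  bimolecular: true,  source: "Padrick 2008", kd_inconsistent: true}
  - {id: 15, description: "GST-VCA:actin binds Arp2/3",                                     k_on: 0.8e6,  k_off: 0.014,  kd_um: 0.018,  bimolecular: true,  source: "Padrick 2008, Beltzner 2008, Kelly 2006"}
  - {id: 16, description: "GST-VCA:actin2 binds Arp2/3",                                    k_on: 0.8e6,  k_off: 0.029,  kd_um: 0.028,  bimolecular: true,  source: "Padrick 2008, Beltzner 2008, Kelly 2006", kd_inconsistent: true}
  - {id: 17, description: "Actin monomer binds GST-VCA:Arp2/3",                             k_on: 2.5e6,  k_off: 3,      kd_um: 1.2,    bimolecular: true,  source: "Marchand 2001, Beltzner 2008"}
  - {id: 18, description: "Actin monomer binds GST-VCA:actin:Arp2/3",                       k_on: 2.5e6,  k_off: 3,      kd_um: 1.2,    bimolecular: true,  source: "Marchand 2001, Beltzner 2008"}
  - {id: 19, description: "GST-VCA:actin2:Arp2/3 binds actin filament (k_fil_on)",          k_on: 1.37e6, k_off: 1.23,   kd_um: 0.9,    bimolecular: true,  source: "Hetrick 2013"}
  - {id: 20, description: "GST-VCA binds Arp2/3:F-actin",                                   k_on: 0.8e6,  k_off: 0.072,  kd_um: 0.009,  bimolecular: true,  source: "Padrick 2008", kd_inconsistent: true}
  - {id: 21, description: "GST-VCA:Arp2/3 binds F-actin",                                   k_on: 1.37e6, k_off: 1.23,   kd_um: 0.9,    bimolecular: true,  source: "Hetrick 2013"}
  - {id: 22, description: "GST-VCA:Arp2/3:actin binds F-actin",                             k_on: 1.37e6, k_off: 1.23,   kd_um: 0.9,    bimolecular: true,  source: "Hetrick 2013"}
  - {id: 23, description: "GST-VCA:Arp2/3:F-actin binds actin monomer",                     k_on: 2.5e6,  k_off: 3,      kd_um: 1.2,    bimolecular: true,  source: "Marchand 2001, Beltzner 2008"}
  - {id: 24, description: "GST-VCA:Arp2/3:actin:F-actin binds actin monomer",               k_on: 2.5e6,  k_off: 3,      kd_um: 1.2,    bimolecular: true,  source: "Marchand 2001, Beltzner 2008"}
  - {id: 25, description: "Arp2/3 complex nucleation (k_nuc)",                              k_on: [0.004, 0.006], default: 0.0038, bimolecular: false, source: "this model"}
  - {id: 26, description: "Cortactin binds actin filament",                                 k_on: 1.21e4, k_off: 0.063,  kd_um: 5.21,   bimolecular: true,  source: "this model"}
  - {id: 27, description: "Cortactin binds nascent branch junction",                        k_on: 2.0e6,  k_off: 0.034,  kd_um: 0.017,  bimolecular: true,  source: "this model"}
  - {id: 28, description: "Synergy displacement activation of Arp2/3 complex (k_dis)",      k_on: 0.036,                          bimolecular: false, source: "this model"}
  - {id: 29, description: "Synergy recycling, cortactin dissociates sequestered GST-VCA",   k_on: 2.0e6,  k_off: 0.034,  kd_um: 0.017,  bimolecular: true,  source: "this model"}
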