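# Calibration of the two-arm replication design: group moments are the
# values reported for the 7-day chloroquine vs vehicle diaphragm NMJ
# study this package models (per-NMJ morphometric means +/- SD, per-animal
# NMJ counts with a floor of 35 en face NMJs, denervation-category
# mixtures, and sex-specific body masses in grams).
seed: 1
mode: fast
groups:
  vehicle:
    nAnimals: 6
    nmjPerAnimalMean: 40      # study average 40 +/- 11 NMJs per animal
    nmjPerAnimalSD: 11
    nmjMin: 35
    preVolumeMean: 1411       # um^3
    preVolumeSD: 236
    endplateVolumeMean: 1792  # um^3
    endplateVolumeSD: 259
    appositionMean: 66        # percent of pre-synaptic volume
    appositionSD: 11
    rpaMean: 45               # relative planar area, percent
    rpaSD: 8
    categoryProbs: [0.93, 0.07, 0.00]
    animalEffectFraction: 0.4
    bodyMass:
      maleMean: 33.3
      maleSD: 2.9
      femaleMean: 22.6
      femaleSD: 1.2
      changeMean: 0.5
      changeSD: 1.2
  chloroquine:
    nAnimals: 6
    nmjPerAnimalMean: 40
    nmjPerAnimalSD: 11
    nmjMin: 35
    preVolumeMean: 1248
    preVolumeSD: 274
    endplateVolumeMean: 1804
    endplateVolumeSD: 269
    appositionMean: 56
    appositionSD: 10
    rpaMean: 43
    rpaSD: 7
    categoryProbs: [0.78, 0.19, 0.03]
    animalEffectFraction: 0.4
    bodyMass:
      maleMean: 30.8
      maleSD: 3.4
      femaleMean: 22.8
      femaleSD: 2.1
      changeMean: -0.2
      changeSD: 1.2
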