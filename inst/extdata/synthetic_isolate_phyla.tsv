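genus	phylum
Genus01	Proteobacteria
Genus02	Bacteroidetes
Genus03	Actinobacteria
Genus04	Firmicutes
Genus05	Proteobacteria
Genus06	Bacteroidetes
Genus07	Actinobacteria
Genus08	Firmicutes
Genus09	Proteobacteria
Genus10	Bacteroidetes
Genus11	Actinobacteria
Genus12	Firmicutes
Genus13	Proteobacteria
Genus14	Bacteroidetes
Genus15	Actinobacteria
Genus16	Firmicutes
Genus17	Proteobacteria
Genus18	Bacteroidetes
Genus19	Actinobacteria
Genus20	Firmicutes
Genus21	Proteobacteria
Genus22	Bacteroidetes
Genus23	Actinobacteria
Genus24	Firmicutes
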