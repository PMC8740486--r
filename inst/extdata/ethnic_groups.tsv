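surface	normalized	group
han	Han	Han
european	European	European
asian	Asian	Asian
african	African	African
caucasian	Caucasian	Caucasian
hispanic	Hispanic	Hispanic
latino	Latino	Latino
ashkenazi	Ashkenazi	Ashkenazi
basque	Basque	Basque
kurdish	Kurdish	Kurdish
tamil	Tamil	Tamil
punjabi	Punjabi	Punjabi
persian	Persian	Persian
arab	Arab	Arab
slavic	Slavic	Slavic
polynesian	Polynesian	Polynesian
melanesian	Melanesian	Melanesian
aboriginal	Aboriginal	Aboriginal
maori	Maori	Maori
inuit	Inuit	Inuit
amerindian	Amerindian	Amerindian
mestizo	Mestizo	Mestizo
bantu	Bantu	Bantu
zulu	Zulu	Zulu
yoruba	Yoruba	Yoruba
uyghur	Uyghur	Uyghur
tibetan	Tibetan	Tibetan
roma	Roma	Roma
bedouin	Bedouin	Bedouin
berber	Berber	Berber
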