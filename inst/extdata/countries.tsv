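surface	normalized	country
japanese	Japanese	Japan
chinese	Chinese	China
american	American	United States
indian	Indian	India
italian	Italian	Italy
turkish	Turkish	Turkey
korean	Korean	South Korea
indonesian	Indonesian	Indonesia
german	German	Germany
french	French	France
spanish	Spanish	Spain
british	British	United Kingdom
english	English	United Kingdom
irish	Irish	Ireland
dutch	Dutch	Netherlands
swedish	Swedish	Sweden
norwegian	Norwegian	Norway
danish	Danish	Denmark
finnish	Finnish	Finland
polish	Polish	Poland
russian	Russian	Russia
greek	Greek	Greece
portuguese	Portuguese	Portugal
brazilian	Brazilian	Brazil
mexican	Mexican	Mexico
canadian	Canadian	Canada
australian	Australian	Australia
thai	Thai	Thailand
vietnamese	Vietnamese	Vietnam
iranian	Iranian	Iran
israeli	Israeli	Israel
egyptian	Egyptian	Egypt
moroccan	Moroccan	Morocco
nigerian	Nigerian	Nigeria
kenyan	Kenyan	Kenya
argentinian	Argentinian	Argentina
chilean	Chilean	Chile
colombian	Colombian	Colombia
pakistani	Pakistani	Pakistan
bangladeshi	Bangladeshi	Bangladesh
nepalese	Nepalese	Nepal
sri lankan	Sri Lankan	Sri Lanka
armenian	Armenian	Armenia
mongolian	Mongolian	Mongolia
swiss	Swiss	Switzerland
new zealander	New Zealander	New Zealand
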