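plot_code,name,lat,lon,cluster,elevation_m,habitat,size_ha,census_year
ALM-01,Altos de Maizal,-11.8,-71.47,Manu,400,terra_firme,2,2008
CUZ-01,Cuzco Amazonico 1,-12.54,-69.06,Cuzco Amazonico,190,floodplain,1,2008
CUZ-02,Cuzco Amazonico 2,-12.54,-69.06,Cuzco Amazonico,190,floodplain,1,2008
CUZ-03,Cuzco Amazonico 3,-12.53,-69.05,Cuzco Amazonico,190,floodplain,1,2008
CUZ-04,Cuzco Amazonico 4,-12.54,-69.05,Cuzco Amazonico,190,floodplain,1,2008
FLP-01,Finca las Piedras,-12.23,-69.11,Finca las Piedras,250,terra_firme,1,2024
LAS-02,Jacaratia Los Amigos,-12.57,-70.09,Los Amigos,235,floodplain,1,2008
MNU-05,Manu alluvial Cocha Cashu Trail 12,-11.88,-71.41,Manu,347,floodplain,2.25,2008
MNU-06,Manu alluvial Cocha Cashu Trail 2 and 31,-11.89,-71.40,Manu,345,floodplain,2.25,2008
POR-01,RESEX Chico Mendes Seringal Porongaba 1,-10.82,-68.77,Acre,268,terra_firme,1,2009
POR-02,RESEX Chico Mendes Seringal Porongaba 2,-10.8,-68.77,Acre,268,terra_firme,1,2009
RFH-01,Reserva Florestal Humaita,-9.75,-67.67,Acre,176,terra_firme,1,2011
TAM-01,Tambopata plot zero,-12.84,-69.29,Tambopata,205,terra_firme,1,2008
TAM-02,Tambopata plot one,-12.83,-69.29,Tambopata,210,terra_firme,1,2008
TAM-04,Tambopata plot two swamp edge clay,-12.84,-69.28,Tambopata,210,terra_firme,0.42,2008
TAM-05,Tambopata plot three,-12.83,-69.27,Tambopata,220,terra_firme,1,2008
TAM-06,Tambopata plot four,-12.84,-69.30,Tambopata,200,floodplain,1,2008
TAM-07,Tambopata plot six,-12.83,-69.26,Tambopata,225,terra_firme,1,2011
TAM-08,Tambopata plot seven,-12.83,-69.27,Tambopata,220,terra_firme,1,2011
TAM-09,Tambopata plot eight,-12.83,-69.28,Tambopata,199,terra_firme,1,2010
TRC-01,Tambopata Research Center,-13.12,-69.62,Tambopata,240,floodplain,1,2020
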