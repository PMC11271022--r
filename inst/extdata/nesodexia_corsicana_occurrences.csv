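id,lat,lon,year,elevation_m,note
sisco,42°48'N,09°26'E,2021,25-300,"Haute-Corse, Sisco"
chioso,42.818467,9.434145,2021,225,"Haute-Corse, Chioso"
cognocoli,41°51'04.4''N,08°54'00.8''E,2021,730,"Corse-du-Sud, D55, Cognocoli-Monticchi"
porto,42.2619,8.8291,1967,,"10 km E Porto"
zonza-1,41°45'39.6''N,9°13'37.2''E,2019,1244,"Zonza, Samulaghia, marshy seep in dry Sapiniere forest"
zonza-2,41°45'40.1''N,9°13'32.9''E,2019,1231,"Zonza, Samulaghia, rocky seep in Sapiniere forest"
campo-di-loro,41.93,8.79,1907,,"type locality 'Campo di Loro'; no published coordinates, georeferenced to the Campo dell'Oro plain near Ajaccio (gazetteer default, overridable)"
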